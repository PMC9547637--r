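Aachen
Augsburg
Bamberg
Bayreuth
Berlin
Bielefeld
Bochum
Bonn
Bottrop
Braunschweig
Bremen
Bremerhaven
Chemnitz
Cottbus
Darmstadt
Dessau
Dortmund
Dresden
Duisburg
Düren
Düsseldorf
Erfurt
Erlangen
Essen
Esslingen
Flensburg
Frankfurt am Main
Freiburg
Fulda
Fürth
Gelsenkirchen
Gera
Gießen
Göttingen
Greifswald
Gütersloh
Hagen
Halle
Hamburg
Hamm
Hanau
Hannover
Heidelberg
Heilbronn
Herne
Hildesheim
Ingolstadt
Jena
Kaiserslautern
Karlsruhe
Kassel
Kempten
Kiel
Koblenz
Köln
Konstanz
Krefeld
Landshut
Leipzig
Leverkusen
Lübeck
Ludwigsburg
Ludwigshafen
Lüneburg
Magdeburg
Mainz
Mannheim
Marburg
Moers
Mönchengladbach
Mülheim
München
Münster
Neubrandenburg
Neuss
Nürnberg
Oberhausen
Offenbach
Oldenburg
Osnabrück
Paderborn
Passau
Pforzheim
Potsdam
Ravensburg
Recklinghausen
Regensburg
Remscheid
Reutlingen
Rosenheim
Rostock
Saarbrücken
Salzgitter
Schwerin
Siegen
Solingen
Stralsund
Stuttgart
Trier
Tübingen
Ulm
Villingen-Schwenningen
Weimar
Wiesbaden
Wilhelmshaven
Witten
Wolfsburg
Worms
Wuppertal
Würzburg
Zwickau
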