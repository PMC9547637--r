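Ackermann
Albrecht
Arnold
Bachmann
Bader
Barth
Bauer
Baumann
Baumgartner
Beck
Becker
Berger
Bergmann
Bertram
Binder
Bischoff
Blum
Böhm
Born
Brandt
Braun
Brenner
Bruns
Buchholz
Burger
Busch
Christ
Conrad
Dietrich
Dietz
Dreher
Ebert
Eckert
Ehlers
Engel
Engelhardt
Ernst
Esser
Fiedler
Fink
Fischer
Förster
Franke
Freitag
Frey
Friedrich
Fritz
Fuchs
Geiger
Gerlach
Geyer
Gläser
Götz
Graf
Groß
Grünewald
Günther
Haas
Hagen
Hahn
Hamann
Hansen
Hartmann
Hauser
Heck
Heinrich
Heinze
Held
Heller
Henke
Hermann
Herrmann
Hertel
Herzog
Hess
Heyer
Hildebrandt
Hoffmann
Hofmann
Holz
Hoppe
Horn
Huber
Hübner
Jäger
Jahn
Janssen
Jung
Jungbluth
Kaiser
Kastner
Kaufmann
Keller
Kern
Kiefer
Kirchner
Klein
Kluge
Koch
Köhler
Kohl
König
Körner
Kramer
Kraus
Krause
Krebs
Kretschmer
Krieger
Krüger
Kuhn
Kunz
Kurz
Lang
Lange
Lehmann
Lenz
Lindemann
Lindner
Lorenz
Ludwig
Lutz
Mahler
Maier
Mann
Martens
Marx
Maurer
Mayer
Meier
Meissner
Menzel
Merkel
Mertens
Metzger
Meyer
Michel
Möller
Mohr
Moser
Müller
Naumann
Neubauer
Neumann
Nickel
Niemann
Noack
Nolte
Otte
Otto
Paul
Peters
Petersen
Pfeiffer
Pohl
Probst
Rapp
Rausch
Reich
Reichert
Reinhardt
Reuter
Richter
Riedel
Ritter
Rohde
Roth
Rudolph
Runge
Sauer
Schäfer
Scharf
Schenk
Scherer
Schilling
Schindler
Schlegel
Schmid
Schmidt
Schmitt
Schmitz
Schneider
Scholz
Schreiber
Schröder
Schubert
Schulte
Schultz
Schulz
Schumacher
Schuster
Schwab
Schwarz
Seidel
Seifert
Simon
Sommer
Stahl
Stark
Steffen
Stein
Steiner
Stephan
Stoll
Strauss
Thiel
Thomas
Ullrich
Ulrich
Vogel
Vogt
Voigt
Volk
Wagner
Walter
Weber
Wegner
Weidner
Weiss
Wendt
Wenzel
Werner
Westphal
Wetzel
Wilhelm
Wille
Winkler
Winter
Wirth
Witt
Wolf
Wolff
Zander
Ziegler
Zimmermann
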