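Alexander
Andreas
Anna
Annika
Anja
Antje
Barbara
Bastian
Beate
Benjamin
Bernd
Bettina
Birgit
Björn
Brigitte
Carina
Carsten
Christian
Christiane
Christina
Christoph
Claudia
Clemens
Daniel
Daniela
David
Dennis
Dieter
Dirk
Dominik
Doris
Eberhard
Elena
Elias
Elisabeth
Elke
Emil
Emilia
Emma
Erik
Erika
Ernst
Eva
Fabian
Felix
Finn
Florian
Frank
Franziska
Friedrich
Gabriele
Georg
Gerhard
Gisela
Greta
Gudrun
Günter
Hanna
Hannes
Hans
Heike
Heinrich
Heinz
Helga
Henrik
Herbert
Hermann
Hilde
Holger
Ines
Inge
Ingrid
Jakob
Jan
Jana
Janina
Jens
Joachim
Johanna
Johannes
Jonas
Jonathan
Julia
Julian
Jürgen
Jutta
Kai
Karin
Karl
Karla
Katharina
Kathrin
Katja
Kerstin
Kilian
Klaus
Kurt
Lara
Lars
Laura
Lea
Lena
Leon
Leonie
Lieselotte
Linda
Lisa
Lothar
Luca
Ludwig
Luisa
Lukas
Manfred
Manuela
Marcel
Marco
Margarete
Maria
Marianne
Marie
Marion
Markus
Marlene
Martin
Martina
Mathilde
Matthias
Max
Maximilian
Melanie
Michael
Michaela
Mila
Miriam
Monika
Moritz
Nadine
Nicole
Niklas
Nils
Nina
Norbert
Ole
Oliver
Oskar
Otto
Patrick
Paul
Paula
Peter
Petra
Philipp
Pia
Rainer
Ralf
Rebecca
Regina
Renate
René
Richard
Rita
Robert
Rolf
Rosa
Rudolf
Ruth
Sabine
Sandra
Sarah
Sebastian
Silke
Simon
Simone
Sofia
Sonja
Stefan
Stefanie
Susanne
Sven
Tanja
Theo
Theresa
Thomas
Thorsten
Tim
Tobias
Torsten
Ulrike
Ursula
Uta
Uwe
Valentin
Vanessa
Vera
Verena
Viktor
Viktoria
Volker
Walter
Werner
Wilhelm
Wolfgang
Yvonne
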