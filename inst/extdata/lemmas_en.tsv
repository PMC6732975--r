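form	lemma
dogs	dog
cats	cat
children	child
families	family
feet	foot
friends	friend
games	game
hands	hand
hearts	heart
hospitals	hospital
lives	life
loved	love
loves	love
loving	love
men	man
mice	mouse
miles	mile
patients	patient
people	person
running	run
runs	run
ran	run
smiles	smile
smiled	smile
strokes	stroke
survivors	survivor
teeth	tooth
topics	topic
tweets	tweet
walked	walk
walking	walk
walks	walk
women	woman
words	word
years	year
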