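form	lemma
children	child
men	man
women	woman
people	person
feet	foot
teeth	tooth
mice	mouse
geese	goose
lives	life
wives	wife
knives	knife
leaves	leaf
halves	half
selves	self
oxen	ox
data	datum
criteria	criterion
phenomena	phenomenon
bacteria	bacterium
analyses	analysis
diagnoses	diagnosis
crises	crisis
theses	thesis
hypotheses	hypothesis
indices	index
matrices	matrix
appendices	appendix
vertebrae	vertebra
fungi	fungus
nuclei	nucleus
stimuli	stimulus
went	go
gone	go
made	make
took	take
taken	take
given	give
gave	give
found	find
saw	see
seen	see
brought	bring
bought	buy
thought	think
told	tell
left	leave
kept	keep
held	hold
felt	feel
met	meet
ran	run
running	run
rose	rise
risen	rise
fell	fall
fallen	fall
grew	grow
grown	grow
began	begin
begun	begin
wrote	write
written	write
spoke	speak
spoken	speak
died	die
dying	die
lying	lie
better	good
best	good
worse	bad
worst	bad
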