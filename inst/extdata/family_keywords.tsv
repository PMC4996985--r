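family	keyword
TTT	tripartite tricarboxylate
TTT	tricarboxylate transport
TTT	tctA
TTT	tctB
TTT	tctC
TRAP	TRAP transporter
TRAP	tripartite ATP-independent
ABC	ABC transporter
ABC	ATP-binding cassette
MRMLE	mandelate racemase
MRMLE	muconate
transposase	transposase
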