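# Redox couple registry, v1.
# e0_prime_mV: standard midpoint potential at pH 7; e_prime_mV: cellular value where known.
# source PAPER = potential printed in the encoded study; LITERATURE = textbook constant.
name	e0_prime_mV	e_prime_mV	n_electrons	source
co2_formate	-432	NA	2	PAPER
h2	-414	NA	2	LITERATURE
nad	-320	-270	2	PAPER
nadp	-320	-370	2	PAPER
fd	-450	NA	2	PAPER
mq	-74	NA	2	PAPER
methylene_thf	-200	NA	2	LITERATURE
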