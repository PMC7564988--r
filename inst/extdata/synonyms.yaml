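# Static keyword synonym lexicon for the synonym paraphrase rule.
# Keys are keywords (mostly action verbs); values are interchangeable
# alternatives drawn from the closed verb inventory.
clean: [wash, scrub, wipe, sponge]
add: [attach, put, set]
help: [assist]
assist: [help]
prepare: [make, fix]
make: [cook, prepare]
cook: [make]
change: [replace, swap]
replace: [change]
wash: [rinse, clean]
brush: [scrub]
set: [put, add]
put: [set]
record: [add]
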