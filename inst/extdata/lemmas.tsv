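closest	close
closer	close
better	good
best	good
worse	bad
worst	bad
made	make
gave	give
took	take
went	go
children	child
teeth	tooth
feet	foot
men	man
women	woman
dentures	denture
nappies	nappy
baths	bath
braces	brace
brushes	brush
beats	beat
breakfasts	breakfast
temperatures	temperature
toilets	toilet
urinals	urinal
fruits	fruit
noodles	noodle
detergents	detergent
diapers	diaper
ventilations	ventilation
crowns	crown
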