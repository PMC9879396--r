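period,n_eagle_correct,n_eagle_as_noneagle,n_noneagle_as_eagle,n_noneagle_correct,n_noimage_as_eagle,n_noimage_as_noneagle
Original configuration,3975,394,9362,53200,0,0
IdentiFlight system update,2134,976,1715,38310,82,100
Equipment issue,10925,5800,14000,147710,158,359
Equipment replacement,14158,2703,35090,117804,306,104
Neural network upgrade,2932,328,23619,125271,4,18
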