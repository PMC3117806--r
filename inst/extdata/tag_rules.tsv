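pattern	tag
^(g|mg|kg|ug|µg)$	NN-MASS
^(mmol|mol|umol|µmol|kmol)$	NN-MOLAR
^(mL|ml|cm3|dm3|m3|L|l|uL|ul|µl|µL|litre|litres|liter|liters)$	NN-VOL
^%$	NN-PERCENT
^(°C|°F|K|deg|degrees)$	NN-TEMP
^(h|hr|hrs|hour|hours|min|mins|minute|minutes|s|sec|secs|second|seconds|d|day|days|week|weeks|overnight)$	NN-TIME
^(eq|equiv|equivs|equivalent|equivalents)$	NN-EQUIV
^[0-9]+(\.[0-9]+)?%$	CD-PERCENT
^-?[0-9]+(\.[0-9]+)?°[CF]$	CD-TEMP
^[0-9]+(\.[0-9]+)?(h|min|s|d)$	CD-TIME
^(oil|oils|oily|solid|solids|crystal|crystals|needle|needles|gum|gums|foam|foams|liquid|liquids|gas|gases|powder|powders|precipitate)$	NN-STATE
^(mixture|mixtures)$	NN-MIXTURE
^(solution|solutions)$	NN-SOLUTION
^×$	TIMES
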