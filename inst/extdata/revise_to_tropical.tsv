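genus	group	element
Calcareoboea	tropical	tropical
Craspedolobium	tropical	tropical
Malania	tropical	tropical
Musella	tropical	tropical
Whytockia	tropical	tropical
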