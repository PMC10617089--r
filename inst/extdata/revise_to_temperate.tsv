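genus	group	element
Calcareoboea	temperate	east_asian
Craspedolobium	temperate	east_asian
Malania	temperate	east_asian
Musella	temperate	east_asian
Whytockia	temperate	east_asian
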