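locus01	500	501	site_locus01	G	T
locus02	500	501	site_locus02	C	A
locus03	500	501	site_locus03	C	A
locus04	500	501	site_locus04	T	G
locus05	500	501	site_locus05	G	T
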