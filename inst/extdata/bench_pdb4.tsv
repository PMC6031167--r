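id	length	aa_seq	hp_seq	e_gat	e_ma
1PJF	46	GVIDTSAVESAITDGQGDMKAIGGYIVGALVILAVAGLIYSMLRKA	HHHPPPHHPPHHPPHPHPHPHHHHPHHHHHHHHHHHHHHPPHHPPH	-25	-58
1AAF	55	MQRGNFRNQRKIIKCFNCGKEGHIAKNCRAPRKRGCWKCGKEGHQMKDCTERQAN	HPPHPHPPPPPHHPPHPPHPPHPHHPPPPHHPPPHPHPPHPPHPPHPPPPPPPHP	-15	-22
2PTL	78	ENKEETPETPETDSEEEVTIKANLIFANGSTQTAEFKGTFEKATSEAYAYADTLKKDNGEYTVDVADKGYTLNIKFAG	PPPPPPHPPHPPPPPPPHPHPHPHHHHPHPPPPHPHPHPHPPHPPPHPHPHPPHPPPPHPPPHPHHPPHPPHPHPHHH	-25	-30
2CQO	119	GSSGSSGMNSGRPETMENLPALYTIFQGEVAMVTDYGAFIKIPGCRKQGLVHRTHMSSCRVDKPSEIVDVGDKVWVKLIGREMKNDRIKVSLSMKVVNQGTGKDLDPNNVIIESGPSSG	HPPHPPHHPPHPHPPHPPHHHHPPHHPHPHHHHPPPHHHHPHHHPPPPHHHPPPPHPPPPHPPHPPHHPHHPPHHHPHHHPPHPPPPHPHPHPHPHHPPHPHPPHPHPPHHHPPHHPPH	-45	-68
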