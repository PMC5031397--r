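name	sequence	orientation
SFF_145f	GTHACHGCYCAYGCHTTYGTAATAAT	forward
SFF_210f	GGAAAYTGRYTARTHCCHYTRATAATTGG	forward
SFF_348f	CMGTHTAYCCYCCYYTAGCAGG	forward
SFF_351f	CMGTHTAYCCHCCHYTAGCAGGAAA	forward
SFF_348r	GCATGDGCDAGRTTYCCNGC	reverse
SFF_351r	CTCCWGCRTGDGCWAGRTTTCC	reverse
SFF_492r	ACDGATCAKACRAAYARKGGTG	reverse
BEGLCOIf	GGYGCYTGAGCHGGWATAGT	forward
BEGLCOIr	ARRATDGGRTCYCCYCCTCC	reverse
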