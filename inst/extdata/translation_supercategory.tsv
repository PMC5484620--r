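term_id	super_category
GO:0006412	translation
GO:0006413	translation
GO:0006414	translation
GO:0006417	translation
GO:0002181	translation
GO:0003735	translation
GO:0022626	translation
GO:0042254	translation
GO:0030154	cell differentiation and development
GO:0032502	cell differentiation and development
GO:0070972	protein localization to the ER
GO:0009966	regulation of signaling response
GO:0050896	response to stimulus
GO:0002377	antibody production
GO:0008152	metabolism
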