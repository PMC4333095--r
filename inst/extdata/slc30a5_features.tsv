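feature	coordinates	start	end	length_bp
EMSA probe	promoter	-156	46	202
ZTRE	promoter	-91	-76	16
ZTRE 5'-side deletion	promoter	-91	-84	8
competitor oligo	promoter	-124	-75	50
18S qPCR amplicon	transcript	92	184	93
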