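family	type	coords	read_pairs	printed_size
1	duplication	chr3:50382561–50403806	22	~21kb
2	deletion	chr16:49741265–49760865	17	~19.6kb
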