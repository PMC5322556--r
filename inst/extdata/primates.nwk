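((((((((Human,Chimp)HomoPan,Gorilla)Homininae,Orangutan)Hominidae,Rhesus)Catarrhini,Marmoset)Anthropoidea,Tarsier)Haplorrhini,(MouseLemur,Bushbaby)Strepsirrhini)Primates,TreeShrew)Root;
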