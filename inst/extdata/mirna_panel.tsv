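name	mature_sequence
miR-8089
miR-4667-5p
miR-4700-5p
miR-6825-5p
miR-3150a-3p
miR-6763-5p
miR-3126-5p
miR-6875-5p
miR-6883-5p
miR-6785-5p
miR-149-3p
miR-4728-5p
miR-4486
miR-6797-5p
miR-1249-5p
cel-miR-39-3p	UCACCGGGUGUAAAUCAGCUUG
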