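sample_id	group	animal_id
CONTROL_1	CONTROL	animal_1
CONTROL_2	CONTROL	animal_2
CONTROL_3	CONTROL	animal_3
CONTROL_4	CONTROL	animal_4
S1_1	S1	animal_1
S1_2	S1	animal_2
S1_3	S1	animal_3
S1_4	S1	animal_4
S6_1	S6	animal_1
S6_2	S6	animal_2
S6_3	S6	animal_3
S6_4	S6	animal_4
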