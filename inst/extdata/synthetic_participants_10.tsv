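# socialign 0.1.0 | seed=20260919 | config=fixture
participant_id	age	gender	u1	u2	u3	h1	h2	h3
1	40	female	1	1	1	7	7	6
2	38	female	5	5	4	2	5	5
3	39	male	2	3	4	1	4	1
4	29	female	1	1	1	4	4	6
5	25	female	1	1	1	5	4	6
6	19	female	7	3	6	3	2	2
7	53	male	2	4	4	6	2	7
8	28	female	2	2	1	7	6	7
9	44	female	3	2	1	5	5	1
10	50	female	1	1	3	4	4	2
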