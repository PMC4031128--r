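#SampleID	Helminth	Trichuris	Ascaris	Hookworm
S001	Pos	Pos	Neg	Neg
S002	Pos	Neg	Pos	Neg
S003	Pos	Pos	Neg	Neg
S004	Pos	Neg	Neg	Neg
S005	Pos	Pos	Pos	Neg
S006	Pos	Pos	Pos	Neg
S007	Pos	Pos	Neg	Pos
S008	Pos	Pos	Pos	Neg
S009	Pos	Neg	Pos	Neg
S010	Neg	Neg	Neg	Neg
S011	Neg	Neg	Neg	Neg
S012	Neg	Neg	Neg	Neg
S013	Neg	Neg	Neg	Neg
S014	Neg	Neg	Neg	Neg
S015	Neg	Neg	Neg	Neg
S016	Neg	Neg	Neg	Neg
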