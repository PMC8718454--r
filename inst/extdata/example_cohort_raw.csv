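respondent_id,Q1,Q2,Q3,Q4,Q5,Q6,Q7,Q8,Q9,Q10,Q11,Q12,Q13,Q14,Q15,Q16,Q17,Q18,Q19,Q20,Q21,Q22,Q23,Q24,Q25,Q26,Q27,Q28,Q29,Q30,Q31,Q32,Q33,Q34,Q35,Q36,Q37,Q38,Q39,Q40,Q41,Q42
V1,3,4,4,4,4,2,2,4,1,4,3,4,4,4,2,3,3,4,2,1,2,4,2,4,1,2,4,3,3,4,4,4,4,4,4,2,4,1,3,1,1,4
V2,4,3,1,4,2,3,4,3,2,3,4,4,2,2,4,1,3,2,3,4,2,4,4,2,4,1,1,4,2,4,1,2,1,1,2,2,3,2,3,2,3,1
V3,4,4,2,1,1,3,1,4,1,1,1,4,1,4,1,2,1,1,1,2,1,3,1,1,3,1,4,1,2,2,2,4,4,1,4,3,1,1,3,1,1,2
V4,3,1,2,3,3,3,1,1,1,2,1,2,1,3,1,1,1,1,1,2,4,1,1,4,1,2,1,1,1,2,4,2,1,1,1,2,3,4,1,1,2,4
V5,3,2,4,1,2,1,3,1,2,3,3,1,1,1,1,1,2,1,2,3,1,3,1,2,2,3,1,1,4,1,3,3,4,3,2,2,2,2,2,3,1,3
V6,3,4,2,1,4,4,1,1,1,2,1,2,1,3,1,1,1,1,1,2,4,1,1,4,4,2,1,1,1,2,4,2,1,1,1,3,3,4,2,1,1,4
V7,2,1,4,3,2,1,1,1,1,3,3,1,1,1,1,1,2,1,1,2,1,3,1,2,1,3,1,1,4,1,2,3,4,3,2,2,2,2,2,1,2,3
V8,4,3,2,1,2,3,3,4,2,1,1,4,1,4,1,1,1,1,2,3,1,3,1,1,2,1,4,1,2,1,2,4,4,1,4,2,1,1,2,3,1,2
V9,3,4,4,4,4,2,2,4,1,4,3,4,4,4,2,3,3,4,3,1,2,4,2,4,1,3,4,3,3,4,4,4,4,4,3,2,4,1,3,1,1,4
V10,4,3,1,3,2,3,4,3,2,3,4,4,2,2,4,1,3,2,2,4,2,4,3,2,4,1,1,4,2,4,1,2,1,1,2,2,4,2,2,2,3,1
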