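fold,train_pos,train_pos_subjects,train_neg,train_neg_subjects,test_pos,test_pos_subjects,test_neg,test_neg_subjects
1,288,41,265,13,134,19,128,6
2,283,41,266,13,139,19,127,6
3,298,39,269,13,124,21,124,6
4,298,40,267,13,124,20,126,6
5,262,41,274,13,160,19,119,6
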