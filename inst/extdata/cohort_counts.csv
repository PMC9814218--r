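set,label,site_a,site_b,total
all,adenocarcinoma,718,603,1321
all,benign,964,0,964
consensus,aggressive,418,372,790
consensus,indolent,81,140,221
consensus,benign,964,0,964
training,aggressive,236,249,485
training,indolent,24,87,111
training,benign,704,0,704
validation,aggressive,5,5,10
validation,indolent,5,5,10
validation,benign,10,0,10
test,aggressive,177,118,295
test,indolent,52,48,100
test,benign,250,0,250
test_predictions,double_label,NA,NA,114
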