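code,sequence,nsub,corrected_nsub,Best_BU,QSBIO_err_prob,homomer,f_id
1abcA,MKVLAWHREDPLST,2,2,1,3.5,TRUE,F1
2defB,GGHIKLMNPQRSTV,1,1,1,8.0,TRUE,F2
3ghiC,MKVLAWHREDPLST,2,2,1,6.1,TRUE,F1
4jklD,AACDEFGHIKLMNP,4,4,1,12.9,TRUE,F3
5mnoE,WWYYVVTTSSRRQQ,6,6,1,0.4,TRUE,F4
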