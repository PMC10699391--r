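logit                                     CORRECT |INCORRECT
  3.00                                             | BFHR NORM
  2.75                                             | PHYS UPFH
  2.50                                             | MHR RANZ UNCOM
  2.25                                             | BFHR DECEL
  2.00                                        PHYS | NORM UPFH
  1.75                                       UNCOM P RANZ
  1.50                                         MHR | DECEL
  1.25                                   NORM UPFH | BFHR
  1.00                                        RANZ | PHYS
  0.75                                 DECEL UNCOM T MHR
  0.50                                        BFHR | NORM
  0.25                                   RANZ UPFH | PHYS
  0.00                                         MHR | UNCOM
 -0.25                             BFHR DECEL NORM | 
 -0.50                                   PHYS UPFH | 
 -0.75                                         MHR | RANZ UNCOM
 -1.00                                       DECEL | BFHR
 -1.25                                   NORM UPFH | PHYS
 -1.50                                       UNCOM | RANZ
 -1.75                                   DECEL MHR | 
 -2.00                              BFHR NORM UPFH | 
 -2.25                                   PHYS RANZ | 
 -2.50                             DECEL MHR UNCOM | 
 -2.75                                   BFHR NORM | 
 -3.00                                   PHYS UPFH | 

T = ability (0.67 logits); P = pass standard (1.76 logits)
flags: PHYS=weakness UPFH=strength MHR=strength UNCOM=weakness RANZ=weakness
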