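target_edge,thickness_lo,thickness_hi,marker_distance,total
2,0,5,10,312
2,0,5,15,344
2,0,5,20,439
2,0,12.5,10,245
2,0,12.5,15,326
2,0,12.5,20,375
2,0,20,10,257
2,0,20,15,273
2,0,20,20,327
3,0,5,10,394
3,0,5,15,397
3,0,5,20,470
3,0,12.5,10,297
3,0,12.5,15,348
3,0,12.5,20,314
3,0,20,10,235
3,0,20,15,269
3,0,20,20,261
4,0,5,10,374
4,0,5,15,410
4,0,5,20,384
4,0,12.5,10,347
4,0,12.5,15,409
4,0,12.5,20,353
4,0,20,10,251
4,0,20,15,331
4,0,20,20,330
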