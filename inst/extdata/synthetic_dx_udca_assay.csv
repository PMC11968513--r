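time_days,replicate,analyte,concentration
1,1,DX,46.599436901544856
7,1,DX,31.421957802721209
14,1,DX,9.1726811059734565
21,1,DX,3.3782906690841727
28,1,DX,5.1109935217848097
35,1,DX,11.99697311958135
42,1,DX,21.999979404177516
49,1,DX,21.770743977413751
56,1,DX,13.149055893978074
63,1,DX,5.0709496928449971
70,1,DX,1.7770455998909254
77,1,DX,0.58242861278037017
84,1,DX,0.17081003351120916
91,1,DX,0.054774975491705701
1,2,DX,45.234880097967235
7,2,DX,32.185111405312021
14,2,DX,9.0547729714587142
21,2,DX,3.1588230778256832
28,2,DX,4.8225373269740057
35,2,DX,12.339911749312011
42,2,DX,21.223463898212483
49,2,DX,21.034958759578842
56,2,DX,12.595388268254828
63,2,DX,5.2006638776897907
70,2,DX,1.797492632129464
77,2,DX,0.55216227552977637
84,2,DX,0.17478622402628421
91,2,DX,0.053139726371801352
1,3,DX,45.773179901860992
7,3,DX,31.374097877000558
14,3,DX,9.1894957409884874
21,3,DX,3.3830929171483821
28,3,DX,5.174960219879865
35,3,DX,11.876074505629589
42,3,DX,21.57008625326014
49,3,DX,21.063008933666637
56,3,DX,12.440551888129381
63,3,DX,4.9909115111558693
70,3,DX,1.6482280041427673
77,3,DX,0.55735970934767376
84,3,DX,0.17641405708753172
91,3,DX,0.054684345020372511
1,1,UDCA,22.274022031306913
7,1,UDCA,9.5567560781123486
14,1,UDCA,1.8048601856097106
21,1,UDCA,2.4543564088121159
28,1,UDCA,17.140457677381669
35,1,UDCA,32.290023511778571
42,1,UDCA,8.0352353072726466
49,1,UDCA,0.83323512610455219
56,1,UDCA,0.072608877066571043
63,1,UDCA,0.0061447446509392684
70,1,UDCA,0.00055653585131122912
77,1,UDCA,4.7225841870577112e-05
84,1,UDCA,4.0367182362385866e-06
91,1,UDCA,3.501670107359022e-07
1,2,UDCA,22.23940985370103
7,2,UDCA,9.715126889940553
14,2,UDCA,1.7445589417670311
21,2,UDCA,2.4471570214460621
28,2,UDCA,17.295230927452415
35,2,UDCA,31.499865584964834
42,2,UDCA,8.1994898939697674
49,2,UDCA,0.84547465063738758
56,2,UDCA,0.071094974501392974
63,2,UDCA,0.0064052339238560695
70,2,UDCA,0.00054315674120251239
77,2,UDCA,4.7594755659170273e-05
84,2,UDCA,4.1036856826771077e-06
91,2,UDCA,3.532616701862312e-07
1,3,UDCA,21.483571859815815
7,3,UDCA,9.680211419457077
14,3,UDCA,1.8787814691382225
21,3,UDCA,2.3868889145697092
28,3,UDCA,17.234042683567466
35,3,UDCA,31.748276791738132
42,3,UDCA,8.2296986905775729
49,3,UDCA,0.83007888571741184
56,3,UDCA,0.070866299575134059
63,3,UDCA,0.0061052986109958653
70,3,UDCA,0.00055585581876758234
77,3,UDCA,4.6866839835230807e-05
84,3,UDCA,4.0366118242076494e-06
91,3,UDCA,3.4739886285014632e-07
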