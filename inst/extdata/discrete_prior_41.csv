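value,prob
-2.0,0.024390243902439025
-1.9,0.024390243902439025
-1.8,0.024390243902439025
-1.7,0.024390243902439025
-1.6,0.024390243902439025
-1.5,0.024390243902439025
-1.4,0.024390243902439025
-1.3,0.024390243902439025
-1.2,0.024390243902439025
-1.1,0.024390243902439025
-1.0,0.024390243902439025
-0.9,0.024390243902439025
-0.8,0.024390243902439025
-0.7,0.024390243902439025
-0.6,0.024390243902439025
-0.5,0.024390243902439025
-0.4,0.024390243902439025
-0.3,0.024390243902439025
-0.2,0.024390243902439025
-0.1,0.024390243902439025
0.0,0.024390243902439025
0.1,0.024390243902439025
0.2,0.024390243902439025
0.3,0.024390243902439025
0.4,0.024390243902439025
0.5,0.024390243902439025
0.6,0.024390243902439025
0.7,0.024390243902439025
0.8,0.024390243902439025
0.9,0.024390243902439025
1.0,0.024390243902439025
1.1,0.024390243902439025
1.2,0.024390243902439025
1.3,0.024390243902439025
1.4,0.024390243902439025
1.5,0.024390243902439025
1.6,0.024390243902439025
1.7,0.024390243902439025
1.8,0.024390243902439025
1.9,0.024390243902439025
2.0,0.024390243902439025
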