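residue,atom,element,x,y,z
ALA,N,N,-0.966,0.493,1.5
ALA,CA,C,0.257,0.418,0.692
ALA,C,C,-0.094,0.017,-0.716
ALA,O,O,-1.056,-0.682,-0.923
ALA,CB,C,1.204,-0.62,1.296
ALA,OXT,O,0.661,0.439,-1.742
A,OP3,O,2.135,-1.141,-5.313
A,P,P,1.024,-0.137,-4.723
A,OP1,O,1.633,1.19,-4.488
A,OP2,O,-0.183,0.005,-5.778
A,O5',O,0.456,-0.72,-3.334
A,C5',C,-0.52,0.209,-2.863
A,C4',C,-1.101,-0.287,-1.538
A,O4',O,-0.064,-0.383,-0.538
A,C3',C,-2.105,0.739,-0.969
A,O3',O,-3.445,0.36,-1.287
A,C2',C,-1.874,0.684,0.558
A,O2',O,-3.065,0.271,1.231
A,C1',C,-0.755,-0.367,0.729
A,N9,N,0.158,0.029,1.803
A,C8,C,1.265,0.813,1.672
A,N7,N,1.843,0.963,2.828
A,C5,C,1.143,0.292,3.773
A,C6,C,1.29,0.091,5.156
A,N6,N,2.344,0.664,5.846
A,N1,N,0.391,-0.656,5.787
A,C2,C,-0.617,-1.206,5.136
A,N3,N,-0.792,-1.051,3.841
A,C4,C,0.056,-0.32,3.126
U,OP3,O,-2.122,1.033,-4.69
U,P,P,-1.03,0.047,-4.037
U,OP1,O,-1.679,-1.228,-3.66
U,OP2,O,0.138,-0.241,-5.107
U,O5',O,-0.399,0.736,-2.726
U,C5',C,0.557,-0.182,-2.196
U,C4',C,1.197,0.415,-0.942
U,O4',O,0.194,0.645,0.074
U,C3',C,2.181,-0.588,-0.301
U,O3',O,3.524,-0.288,-0.686
U,C2',C,1.995,-0.383,1.218
U,O2',O,3.219,0.046,1.819
U,C1',C,0.922,0.723,1.319
U,N1,N,0.028,0.464,2.451
U,C2,C,-0.69,-0.671,2.486
U,O2,O,-0.587,-1.474,1.58
U,N3,N,-1.515,-0.936,3.517
U,C4,C,-1.641,-0.055,4.53
U,O4,O,-2.391,-0.292,5.46
U,C5,C,-0.894,1.146,4.502
U,C6,C,-0.07,1.384,3.459
G,OP3,O,-1.945,-1.36,5.599
G,P,P,-0.911,-0.277,5.008
G,OP1,O,-1.598,1.022,4.844
G,OP2,O,0.325,-0.105,6.025
G,O5',O,-0.365,-0.78,3.58
G,C5',C,0.542,0.217,3.109
G,C4',C,1.1,-0.2,1.748
G,O4',O,0.033,-0.318,0.782
G,C3',C,2.025,0.898,1.182
G,O3',O,3.395,0.582,1.439
G,C2',C,1.741,0.884,-0.338
G,O2',O,2.927,0.56,-1.066
G,C1',C,0.675,-0.22,-0.507
G,N9,N,-0.297,0.162,-1.534
G,C8,C,-1.44,0.88,-1.334
G,N7,N,-2.066,1.037,-2.464
G,C5,C,-1.364,0.431,-3.453
G,C6,C,-1.556,0.279,-4.846
G,O6,O,-2.534,0.755,-5.397
G,N1,N,-0.626,-0.401,-5.551
G,C2,C,0.459,-0.934,-4.923
G,N2,N,1.384,-1.626,-5.664
G,N3,N,0.649,-0.8,-3.63
G,C4,C,-0.226,-0.134,-2.868
C,OP3,O,2.147,-1.021,-4.678
C,P,P,1.049,-0.039,-4.028
C,OP1,O,1.692,1.237,-3.646
C,OP2,O,-0.116,0.246,-5.102
C,O5',O,0.415,-0.733,-2.721
C,C5',C,-0.546,0.181,-2.193
C,C4',C,-1.189,-0.419,-0.942
C,O4',O,-0.19,-0.648,0.076
C,C3',C,-2.178,0.583,-0.307
C,O3',O,-3.518,0.283,-0.703
C,C2',C,-2.001,0.373,1.215
C,O2',O,-3.228,-0.059,1.806
C,C1',C,-0.924,-0.729,1.317
C,N1,N,-0.036,-0.47,2.453
C,C2,C,0.652,0.683,2.514
C,O2,O,0.529,1.504,1.62
C,N3,N,1.467,0.945,3.535
C,C4,C,1.62,0.07,4.52
C,N4,N,2.464,0.35,5.569
C,C5,C,0.916,-1.151,4.483
C,C6,C,0.087,-1.399,3.442
DA,OP3,O,1.845,-1.282,-5.339
DA,P,P,0.934,-0.156,-4.636
DA,OP1,O,1.781,0.996,-4.255
DA,OP2,O,-0.204,0.331,-5.665
DA,O5',O,0.241,-0.771,-3.32
DA,C5',C,-0.549,0.27,-2.744
DA,C4',C,-1.239,-0.251,-1.482
DA,O4',O,-0.267,-0.564,-0.458
DA,C3',C,-2.105,0.859,-0.835
DA,O3',O,-3.409,0.895,-1.418
DA,C2',C,-2.173,0.398,0.64
DA,C1',C,-0.965,-0.545,0.797
DA,N9,N,-0.078,-0.047,1.852
DA,C8,C,0.962,0.817,1.689
DA,N7,N,1.535,1.044,2.835
DA,C5,C,0.897,0.346,3.805
DA,C6,C,1.069,0.196,5.191
DA,N6,N,2.079,0.869,5.856
DA,N1,N,0.236,-0.603,5.85
DA,C2,C,-0.729,-1.249,5.224
DA,N3,N,-0.925,-1.144,3.927
DA,C4,C,-0.142,-0.368,3.184
DT,OP3,O,-3.912,-2.311,1.636
DT,P,P,-3.968,-1.665,3.118
DT,OP1,O,-4.406,-2.599,4.208
DT,OP2,O,-4.901,-0.36,2.92
DT,O5',O,-2.493,-1.028,3.315
DT,C5',C,-2.005,-0.136,2.327
DT,C4',C,-0.611,0.328,2.728
DT,O4',O,0.247,-0.829,2.764
DT,C3',C,0.008,1.286,1.72
DT,O3',O,0.965,2.121,2.368
DT,C2',C,0.71,0.36,0.754
DT,C1',C,1.157,-0.778,1.657
DT,N1,N,1.164,-2.047,0.989
DT,C2,C,2.333,-2.544,0.374
DT,O2,O,3.41,-1.945,0.363
DT,N3,N,2.194,-3.793,-0.24
DT,C4,C,1.047,-4.57,-0.3
DT,O4,O,0.995,-5.663,-0.857
DT,C5,C,-0.143,-3.98,0.369
DT,C7,C,-1.42,-4.757,0.347
DT,C6,C,-0.013,-2.784,0.958
DG,OP3,O,-1.603,-1.547,5.624
DG,P,P,-0.818,-0.321,4.935
DG,OP1,O,-1.774,0.766,4.63
DG,OP2,O,0.312,0.224,5.941
DG,O5',O,-0.126,-0.826,3.572
DG,C5',C,0.55,0.3,3.011
DG,C4',C,1.233,-0.113,1.706
DG,O4',O,0.253,-0.471,0.705
DG,C3',C,1.976,1.091,1.073
DG,O3',O,3.294,1.218,1.612
DG,C2',C,2.026,0.692,-0.421
DG,C1',C,0.897,-0.345,-0.573
DG,N9,N,-0.068,0.111,-1.575
DG,C8,C,-1.172,0.877,-1.341
DG,N7,N,-1.804,1.094,-2.458
DG,C5,C,-1.145,0.482,-3.472
DG,C6,C,-1.361,0.377,-4.866
DG,O6,O,-2.321,0.914,-5.391
DG,N1,N,-0.473,-0.327,-5.601
DG,C2,C,0.593,-0.928,-5.003
DG,N2,N,1.474,-1.643,-5.774
DG,N3,N,0.804,-0.839,-3.709
DG,C4,C,-0.027,-0.152,-2.917
DC,OP3,O,1.941,-1.055,-4.672
DC,P,P,0.987,-0.017,-3.894
DC,OP1,O,1.802,1.099,-3.365
DC,OP2,O,-0.119,0.56,-4.91
DC,O5',O,0.255,-0.772,-2.674
DC,C5',C,-0.571,0.196,-2.027
DC,C4',C,-1.3,-0.459,-0.852
DC,O4',O,-0.363,-0.863,0.171
DC,C3',C,-2.206,0.569,-0.129
DC,O3',O,-3.488,0.649,-0.756
DC,C2',C,-2.322,-0.04,1.288
DC,C1',C,-1.106,-0.981,1.395
DC,N1,N,-0.267,-0.584,2.528
DC,C2,C,0.27,0.648,2.563
DC,O2,O,0.052,1.424,1.647
DC,N3,N,1.037,1.035,3.581
DC,C4,C,1.291,0.212,4.589
DC,N4,N,2.085,0.622,5.635
DC,C5,C,0.746,-1.088,4.58
DC,C6,C,-0.035,-1.465,3.541
HOH,O,O,-0.064,0.0,0.0
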