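"site","Ricketts Point","Williamstown","Jawbone","Altona","Kirk Point","Avalon","Point Henry","Grand Scenic","Point Richards","Edwards Point","North Swan Bay","South Swan Bay","Point Lonsdale","Mud Islands","Blairgowrie","Rosebud"
"Ricketts Point",0,0.027,0.028,0.03,0.02,0.007,0.001,0.003,0.018,0.084,0.003,0,0.002,0.02,0.019,0.015
"Williamstown",0.027,0,0.041,0.031,0.025,0.009,0.001,0.012,0.043,0.101,0.003,0,0.002,0.059,0.079,0.029
"Jawbone",0.028,0.041,0,0.049,0.023,0.01,0.001,0.02,0.053,0.153,0.003,0,0.003,0.087,0.11,0.03
"Altona",0.03,0.031,0.049,0,0.02,0.011,0,0.018,0.029,0.107,0.003,0,0.002,0.065,0.07,0.02
"Kirk Point",0.02,0.025,0.023,0.02,0,0.175,0.087,0.737,1.885,0.265,0.026,0,0.007,0.148,0.172,4.975
"Avalon",0.007,0.009,0.01,0.011,0.175,0,1.16,4.037,1.221,0.018,0.002,0,0,0.006,0.006,0.003
"Point Henry",0.001,0.001,0.001,0,0.087,1.16,0,0.657,0.229,0,0,0,0,0.001,0.001,0
"Grand Scenic",0.003,0.012,0.02,0.018,0.737,4.037,0.657,0,10.297,0.908,0.073,0,0.017,0.261,0.249,0.127
"Point Richards",0.018,0.043,0.053,0.029,1.885,1.221,0.229,10.297,0,3.104,0.258,0,0.06,1.182,1.278,0.762
"Edwards Point",0.084,0.101,0.153,0.107,0.265,0.018,0,0.908,3.104,0,0.598,0,0.061,0.591,1.649,0.756
"North Swan Bay",0.003,0.003,0.003,0.003,0.026,0.002,0,0.073,0.258,0.598,0,1.752,0.014,0.05,0.073,0.011
"South Swan Bay",0,0,0,0,0,0,0,0,0,0,1.752,0,0,0,0,0
"Point Lonsdale",0.002,0.002,0.003,0.002,0.007,0,0,0.017,0.06,0.061,0.014,0,0,0.04,0.124,0.019
"Mud Islands",0.02,0.059,0.087,0.065,0.148,0.006,0.001,0.261,1.182,0.591,0.05,0,0.04,0,2.392,0.798
"Blairgowrie",0.019,0.079,0.11,0.07,0.172,0.006,0.001,0.249,1.278,1.649,0.073,0,0.124,2.392,0,0.349
"Rosebud",0.015,0.029,0.03,0.02,4.975,0.003,0,0.127,0.762,0.756,0.011,0,0.019,0.798,0.349,0
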