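subject_id,y
S000001,27.7992
S000002,42.921
S000003,20.0184
S000004,22.6849
S000005,30.3702
S000006,29.46
S000007,24.5009
S000008,25.0967
S000009,44.4203
S000010,18.2472
S000011,44.9216
S000012,20.5481
S000013,42.6198
S000014,36.5736
S000015,28.0129
S000016,30.0158
S000017,39.3967
S000018,25.6504
S000019,23.0816
S000020,38.2509
S000021,13.2991
S000022,27.2774
S000023,38.2077
S000024,45.1807
S000025,40.1277
S000026,30.269
S000027,46.8086
S000028,25.2951
S000029,38.4785
S000030,25.1674
S000031,19.29
S000032,42.7316
S000033,33.5436
S000034,26.5982
S000035,33.1064
S000036,31.8504
S000037,37.4152
S000038,29.7244
S000039,14.1779
S000040,21.1114
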