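gene	copy	condition	fpkm
sox-1	1	S0_pH2.5_day3	7109.8422939167
sox-2	1	S0_pH2.5_day3	586.728583354257
tetH	1	S0_pH2.5_day3	583.101834509668
doxD	1	S0_pH2.5_day3	70.884231644213
sqr	1	S0_pH2.5_day3	1781.26080728336
sdo-1	1	S0_pH2.5_day3	562.36421590704
sdo-2	1	S0_pH2.5_day3	19.6589760927873
sdo-3	1	S0_pH2.5_day3	7.2912843203484
sor	1	S0_pH2.5_day3	16.4553797142137
rhd-1	1	S0_pH2.5_day3	444.09430475832
rhd-2	1	S0_pH2.5_day3	248.054013117806
hdrA-1	1	S0_pH2.5_day3	2703.40777566183
hdrA-2	1	S0_pH2.5_day3	3205.80520154167
hdrA-3	1	S0_pH2.5_day3	2034.97570051022
hdrB	1	S0_pH2.5_day3	1035.30394569018
hdrC	1	S0_pH2.5_day3	1059.11045260091
aps	1	S0_pH2.5_day3	11.6863026563863
paps	1	S0_pH2.5_day3	9.73433458719791
sox-1	1	S0_pH1.5_day5	416.51684613805
sox-2	1	S0_pH1.5_day5	1954.40826617221
tetH	1	S0_pH1.5_day5	772.665150524825
doxD	1	S0_pH1.5_day5	23.9202366776109
sqr	1	S0_pH1.5_day5	1848.64425955543
sdo-1	1	S0_pH1.5_day5	270.744087800037
sdo-2	1	S0_pH1.5_day5	26.5663265963629
sdo-3	1	S0_pH1.5_day5	9.44085668795847
sor	1	S0_pH1.5_day5	14.4553993424066
rhd-1	1	S0_pH1.5_day5	230.484024728907
rhd-2	1	S0_pH1.5_day5	827.571373211646
hdrA-1	1	S0_pH1.5_day5	22028.2007017046
hdrA-2	1	S0_pH1.5_day5	2404.37780789518
hdrA-3	1	S0_pH1.5_day5	26266.9356516397
hdrB	1	S0_pH1.5_day5	1271.1192260107
hdrC	1	S0_pH1.5_day5	1493.73514265098
aps	1	S0_pH1.5_day5	7.5461303139117
paps	1	S0_pH1.5_day5	16.1419505050506
sox-1	1	thio_pH2.5_day5	12834.5864498742
sox-2	1	thio_pH2.5_day5	7249.74350563328
tetH	1	thio_pH2.5_day5	5971.38902206817
doxD	1	thio_pH2.5_day5	12.5987056497225
sqr	1	thio_pH2.5_day5	2829.39012078776
sdo-1	1	thio_pH2.5_day5	334.433020748817
sdo-2	1	thio_pH2.5_day5	17.6634109014831
sdo-3	1	thio_pH2.5_day5	8.8798576566251
sor	1	thio_pH2.5_day5	7.92836820036504
rhd-1	1	thio_pH2.5_day5	306.121727691915
rhd-2	1	thio_pH2.5_day5	752.339162223791
hdrA-1	1	thio_pH2.5_day5	2714.25086645984
hdrA-2	1	thio_pH2.5_day5	3509.08011237805
hdrA-3	1	thio_pH2.5_day5	1343.40867115808
hdrB	1	thio_pH2.5_day5	1670.40480411217
hdrC	1	thio_pH2.5_day5	1221.83304359359
aps	1	thio_pH2.5_day5	7.35262317415247
paps	1	thio_pH2.5_day5	11.7123518054925
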