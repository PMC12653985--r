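Assay,Marker,c,Dye,Na,Chromosome,HitFrom,HitTo,Strand,Motif,Repeats,XLinked
1,Myzper-023,0.1,VIC,3,chr1,23347209,23347245,plus,TAT,12,FALSE
1,Myzper-064,0.2,6-FAM,3,chr4,4678265,4678295,plus,ATT,10,FALSE
1,Myzper-095,0.1,VIC,7,chr2,59306409,59306454,plus,CAA,15,TRUE
1,Myzper-112,0.3,PET,3,chr6,18695671,18695695,plus,AAT,8,FALSE
1,Myzper-121,0.2,VIC,4,chr2,17196081,17196051,minus,ACA,10,TRUE
1,Myzper-131,0.1,6-FAM,4,chr6,9082535,9082556,plus,CGG,7,FALSE
1,Myzper-137,0.2,6-FAM,3,chr2,6492290,6492314,plus,AAT,8,TRUE
1,Myzper-146,0.2,NED,3,chr2,31378493,31378526,plus,TAA,11,TRUE
1,Myzper-180,0.2,6-FAM,4,chr6,23237826,23237802,minus,CGC,8,FALSE
1,Myzper-207,0.1,6-FAM,2,chr1,10650144,10650165,plus,GGA,7,FALSE
1,Myzper-209,0.2,NED,6,chr4,21197304,21197328,plus,ATG,8,FALSE
1,Myzper-231,0.3,PET,3,chr2,81831810,81831765,minus,ACCTA,9,TRUE
2,Myzper-016,0.1,6-FAM,3,chr4,6305555,6305531,minus,GTC,8,FALSE
2,Myzper-025,0.3,PET,4,chr3,51486311,51486347,plus,TAA,12,FALSE
2,Myzper-054,0.1,6-FAM,4,chr6,6395254,6395221,minus,TTG,11,FALSE
2,Myzper-060,0.2,NED,3,chr4,20391192,20391216,plus,ATT,8,FALSE
2,Myzper-061,0.1,6-FAM,6,chr3,39954022,39954050,plus,GTGC,7,FALSE
2,Myzper-066,0.1,VIC,4,chr2,17970961,17970991,plus,AAT,10,TRUE
2,Myzper-073,0.1,6-FAM,3,chr3,47724216,47724186,minus,ATT,10,FALSE
2,Myzper-172,0.2,NED,4,chr4,6063778,6063733,minus,ATT,15,FALSE
2,Myzper-174,0.2,NED,4,chr2,2303608,2303638,plus,ATT,10,TRUE
2,Myzper-182,0.1,VIC,4,chr5,28211033,28211063,plus,CCG,10,FALSE
2,Myzper-197,0.3,PET,2,chr3,40651902,40651875,minus,TTA,9,FALSE
2,Myzper-208,0.3,6-FAM,3,chr1,70791470,70791451,minus,TTA,10,FALSE
2,Myzper-212,0.3,PET,3,chr6,12847813,12847789,minus,TAT,8,FALSE
3,Myzper-028,0.1,6-FAM,8,chr4,26556362,26556326,minus,TGC,12,FALSE
3,Myzper-040,0.2,NED,6,chr6,1510305,1510338,plus,CTG,11,FALSE
3,Myzper-047,0.2,PET,4,chr1,11044892,11044922,plus,ATA,10,FALSE
3,Myzper-106,0.2,6-FAM,3,chr1,36719415,36719394,minus,CCG,7,FALSE
3,Myzper-148,0.3,PET,3,chr1,18060929,18060953,plus,TCG,8,FALSE
3,Myzper-166,0.1,VIC,5,chr1,31830661,31830691,plus,ATT,10,FALSE
3,Myzper-191,0.2,6-FAM,4,chr4,2355865,2355889,plus,CAG,8,FALSE
3,Myzper-200,0.2,VIC,3,chr3,34124313,34124280,minus,ATT,11,FALSE
3,Myzper-214,0.2,NED,3,chr1,33520102,33520123,plus,GAC,7,FALSE
3,Myzper-215,0.2,VIC,4,chr2,30879299,30879248,minus,CAA,17,TRUE
3,Myzper-244,0.1,6-FAM,3,chr4,58683634,58683604,minus,TAT,10,FALSE
3,Myzper-257,0.1,6-FAM,2,chr6,6832400,6832376,minus,TCG,8,FALSE
4,Myzper-002,0.1,6-FAM,6,chr4,57017450,57017471,plus,CGC,7,FALSE
4,Myzper-003,0.3,PET,7,chr6,10043860,10043809,minus,TAA,17,FALSE
4,Myzper-014,0.1,NED,2,chr5,286153,286177,plus,ATT,8,FALSE
4,Myzper-031,0.1,VIC,4,chr2,51632413,51632389,minus,TCG,8,TRUE
4,Myzper-032,0.2,NED,2,chr6,17071054,17071075,plus,CGT,7,FALSE
4,Myzper-052,0.1,VIC,5,chr1,75106271,75106244,minus,GCG,9,FALSE
4,Myzper-071,0.2,6-FAM,5,chr2,18003582,18003558,minus,TCC,8,TRUE
4,Myzper-154,0.2,6-FAM,2,chr1,2532569,2532596,plus,TAT,9,FALSE
4,Myzper-162,0.1,6-FAM,6,chr5,22618169,22618148,minus,CCG,7,FALSE
4,Myzper-170,0.3,PET,6,chr4,17291633,17291612,minus,ATA,7,FALSE
4,Myzper-195,0.2,NED,6,chr2,22424405,22424429,plus,CTG,8,TRUE
4,Myzper-268,0.2,VIC,3,chr4,65308976,65308952,minus,GAC,8,FALSE
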