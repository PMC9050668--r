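# Published aggregate columns of a cohort life table for UK companion dogs
# (30,563 deaths, observation window 2016-01-01 to 2020-07-31): deaths per
# one-year age interval (d) and mean fraction of the last year of life lived
# by dogs dying in the interval (a_hat). The final row (x_start = 20) is the
# open "20 and over" interval; its a_hat is the mean years lived past 20.
# All other life-table columns are recomputed from these two.
x_start,d,a_hat
0,514,0.42
1,481,0.52
2,482,0.45
3,489,0.48
4,559,0.48
5,677,0.47
6,892,0.46
7,1254,0.51
8,1730,0.50
9,2265,0.49
10,2852,0.48
11,3449,0.50
12,3645,0.47
13,3785,0.48
14,3126,0.44
15,2249,0.43
16,1253,0.39
17,542,0.38
18,218,0.32
19,78,0.33
20,23,0.46
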