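# Synthetic 12-vertex weighted regulatory network (directed; constructed
# for examples and tests of the linear-threshold family — it is NOT a
# published biological network). Columns: from  to  weight.
1	2	1
2	3	2
3	4	1
4	5	-1
5	6	1
6	7	-2
7	8	1
8	9	1
9	10	-1
10	11	1
11	12	2
12	1	-1
1	5	1
2	7	-1
3	9	1
4	11	-1
5	1	2
6	12	1
7	3	-1
8	2	1
9	6	-1
10	4	1
11	8	-1
12	10	1
6	6	1
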