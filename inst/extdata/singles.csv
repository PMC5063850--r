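compound_id,decision,rationale
1,TN,expert decision based on this single case
7,TN,expert decision based on this single case
20,TN,expert decision based on this single case
22,TN,expert decision based on this single case
28,TN,expert decision based on this single case
30,TN,expert decision based on this single case
32,TN,expert decision based on this single case
36,TN,expert decision based on this single case
39,TN,expert decision based on this single case
43,TN,expert decision based on this single case
56,TN,expert decision based on this single case
57,TN,expert decision based on this single case
58,TN,expert decision based on this single case
62,TN,expert decision based on this single case
63,TN,expert decision based on this single case
70,TN,expert decision based on this single case
75,TN,expert decision based on this single case
78,TN,expert decision based on this single case
79,TN,expert decision based on this single case
80,TN,expert decision based on this single case
81,TN,expert decision based on this single case
89,TN,expert decision based on this single case
96,TN,expert decision based on this single case
102,TN,expert decision based on this single case
106,TN,expert decision based on this single case
109,TN,expert decision based on this single case
113,TN,expert decision based on this single case
118,TN,expert decision based on this single case
119,TN,expert decision based on this single case
122,TN,expert decision based on this single case
130,TN,expert decision based on this single case
134,TP,expert decision based on this single case
136,TN,expert decision based on this single case
138,TN,expert decision based on this single case
141,TN,expert decision based on this single case
151,TN,expert decision based on this single case
153,TN,expert decision based on this single case
160,TN,expert decision based on this single case
169,TP,expert decision based on this single case
177,TP,expert decision based on this single case
196,TN,expert decision based on this single case
197,TN,expert decision based on this single case
198,TN,expert decision based on this single case
213,TP,expert decision based on this single case
216,TN,expert decision based on this single case
223,TN,expert decision based on this single case
225,TN,expert decision based on this single case
232,TN,expert decision based on this single case
234,TN,expert decision based on this single case
238,TN,expert decision based on this single case
258,TP,expert decision based on this single case
261,TN,expert decision based on this single case
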