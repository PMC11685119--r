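name	row	col	x	y
FP1	0	3	-0.25	1
FPZ	0	4	0	1
FP2	0	5	0.25	1
AF3	1	3	-0.25	0.75
AF4	1	5	0.25	0.75
F7	2	0	-1	0.5
F5	2	1	-0.75	0.5
F3	2	2	-0.5	0.5
F1	2	3	-0.25	0.5
FZ	2	4	0	0.5
F2	2	5	0.25	0.5
F4	2	6	0.5	0.5
F6	2	7	0.75	0.5
F8	2	8	1	0.5
FT7	3	0	-1	0.25
FC5	3	1	-0.75	0.25
FC3	3	2	-0.5	0.25
FC1	3	3	-0.25	0.25
FCZ	3	4	0	0.25
FC2	3	5	0.25	0.25
FC4	3	6	0.5	0.25
FC6	3	7	0.75	0.25
FT8	3	8	1	0.25
T7	4	0	-1	0
C5	4	1	-0.75	0
C3	4	2	-0.5	0
C1	4	3	-0.25	0
CZ	4	4	0	0
C2	4	5	0.25	0
C4	4	6	0.5	0
C6	4	7	0.75	0
T8	4	8	1	0
TP7	5	0	-1	-0.25
CP5	5	1	-0.75	-0.25
CP3	5	2	-0.5	-0.25
CP1	5	3	-0.25	-0.25
CPZ	5	4	0	-0.25
CP2	5	5	0.25	-0.25
CP4	5	6	0.5	-0.25
CP6	5	7	0.75	-0.25
TP8	5	8	1	-0.25
P7	6	0	-1	-0.5
P5	6	1	-0.75	-0.5
P3	6	2	-0.5	-0.5
P1	6	3	-0.25	-0.5
PZ	6	4	0	-0.5
P2	6	5	0.25	-0.5
P4	6	6	0.5	-0.5
P6	6	7	0.75	-0.5
P8	6	8	1	-0.5
PO7	7	1	-0.75	-0.75
PO5	7	2	-0.5	-0.75
PO3	7	3	-0.25	-0.75
POZ	7	4	0	-0.75
PO4	7	5	0.25	-0.75
PO6	7	6	0.5	-0.75
PO8	7	7	0.75	-0.75
CB1	8	2	-0.5	-1
O1	8	3	-0.25	-1
OZ	8	4	0	-1
O2	8	5	0.25	-1
CB2	8	6	0.5	-1
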