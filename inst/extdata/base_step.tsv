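# Sequence-dependent base-step geometry for the sequence-to-structure dsDNA
# builder.  Columns: step twist(deg) roll(deg) tilt(deg) shift(A) slide(A)
# rise(A).  Representative B-DNA dinucleotide averages; substitute your own
# table (same schema) for a different calibration.
step	twist	roll	tilt	shift	slide	rise
AA	35.1	0.7	-0.9	0.01	-0.2	3.27
AC	31.5	0.7	0.3	0.13	-0.4	3.36
AG	31.9	4.5	-0.8	0.09	-0.3	3.34
AT	29.3	1.1	0.0	0.00	-0.6	3.31
CA	37.3	4.7	0.5	0.09	0.5	3.33
CC	32.9	3.6	0.1	0.05	-0.2	3.42
CG	36.1	5.4	0.0	0.00	0.4	3.39
CT	31.9	4.5	0.8	-0.09	-0.3	3.34
GA	36.3	1.9	-0.6	-0.02	-0.1	3.37
GC	33.6	0.3	0.0	0.00	-0.4	3.40
GG	32.9	3.6	-0.1	-0.05	-0.2	3.42
GT	31.5	0.7	-0.3	-0.13	-0.4	3.36
TA	37.8	3.3	0.0	0.00	0.1	3.42
TC	36.3	1.9	0.6	0.02	-0.1	3.37
TG	37.3	4.7	-0.5	-0.09	0.5	3.33
TT	35.1	0.7	0.9	-0.01	-0.2	3.27
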