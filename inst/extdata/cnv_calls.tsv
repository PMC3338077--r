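sample_id	call
488-p1	+1q21.1-qter
488-p1	-13q14.12-qter
488-p1	-17q12-q21.32
488-p2	+1q21.1-qter
488-p2	-13q14.12-qter
488-p2	-2q35-q37.3
488-p2	-17q12-q21.32
488-p4	+1q21.1-qter
488-p4	-13q14.12-qter
488-p4	-2q35-q37.3
488-p4	-17q12-q21.32
488-p7	+1q21.1-qter
488-p7	-13q14.12-qter
488-p7	-2q35-q37.3
488-p7	-17q12-q21.32
488-p11	+1q21.1-qter
488-p11	-13q14.12-qter
488-p11	-2q35-q37.3
488-p14	+1q21.1-qter
488-p14	-13q14.12-qter
488-p14	-2q35-q37.3
488-p14	+17
445-p0	-2q35-q37.3 (uncontinuous)
445-p0	+8
445-p0	+15
445-p0	+17q21.32-qter
445-p1	-2q35-q37.3 (uncontinuous)
445-p1	+8
445-p1	+15
445-p1	+17q21.32-qter
445-p4	-2q35-q37.3 (uncontinuous)
445-p4	+8
445-p4	+15
445-p4	+17q21.32-qter
445-p11	-2q35-q37.3 (uncontinuous)
445-p11	+8
445-p11	+15
445-p11	+17q21.32-qter
445-p15	-2q35-q37.3 (uncontinuous)
445-p15	+8
445-p15	+15
445-p15	+17q21.32-qter
445-p22	-2q35-q37.3 (uncontinuous)
445-p22	+8
445-p22	+15
445-p22	+17q21.32-qter
451-p0	-1q24.3-q25.2
451-p0	-3p12.3-p24.3
451-p0	-9p21.3
451-p4	-1q24.3-q25.2
451-p4	-3p12.3-p24.3
451-p4	-9p21.3
451-p11	-1q24.3-q25.2
451-p11	-3p12.3-p24.3
451-p11	-9p21.3
451-p11	+4q13.3-qter
451-p11	-17p
451-p15	-1q24.3-q25.2
451-p15	-3p12.3-p24.3
451-p15	-9p21.3
451-p15	+4q13.3-qter
451-p15	-17p
451-p18	-1q24.3-q25.2
451-p18	-3p12.3-p24.3
451-p18	-9p21.3
451-p18	+4q13.3-qter
451-p18	-17p
451-p21	-1q24.3-q25.2
451-p21	-3p12.3-p24.3
451-p21	-9p21.3
451-p21	+4q13.3-qter
451-p21	-17p
455-p0	+1q
455-p0	-16q
455-p0	-9p21.3
455-p1	+1q
455-p1	-16q
455-p1	-9p21.3
455-p5	+1q
455-p5	-16q
455-p5	-9p21.3
455-p5	-13
455-p11	+1q
455-p11	-16q
455-p11	-9p21.3
455-p11	-13
455-p17	+1q
455-p17	-16q
455-p17	-9p21.3
455-p17	-13
455-p25	+1q
455-p25	-16q
455-p25	-9p21.3
455-p25	-13
455-p25	-Xq21.1
430-PRI-p0	-9p21.3
430-PRI-p1	-9p21.3
430-PRI-p1	+8p11.21-p21.2
430-PRI-p1	+8q
430-PRI-p4	-9p21.3
430-PRI-p4	+8p11.21-p21.2
430-PRI-p4	+8q
430-PRI-p9	-9p21.3
430-PRI-p9	+8p11.21-p21.2
430-PRI-p9	+8q
430-PRI-p19	-9p21.3
430-PRI-p19	+8p11.21-p21.2
430-PRI-p19	+8q
430-MET-p1	-9p21.3
430-MET-p1	-1p36.12-pter
430-MET-p4	-9p21.3
430-MET-p4	-1p36.12-pter
430-MET-p14	-9p21.3
430-MET-p14	-1p36.21-pter
430-MET-p14	-1p13.3-p31.1
430-MET-p14	-5q
430-MET-p14	-11q13.4-q24.3
430-MET-p14	-Xq12-q26.3
430-MET-p21	-9p21.3
430-MET-p21	-1p36.21-pter
430-MET-p21	-1p13.3-p31.1
430-MET-p21	-5q
430-MET-p21	-11q13.4-q24.3
430-MET-p21	-Xq12-q26.3
430-MET-p21	+8p11.21-p21.2
430-MET-p21	+8q
430-MET-p30	-9p21.3
430-MET-p30	-1p36.21-pter
430-MET-p30	-1p13.3-p31.1
430-MET-p30	-5q
430-MET-p30	-11q13.4-q24.3
430-MET-p30	-Xq12-q26.3
430-MET-p30	+8p11.21-p21.2
430-MET-p30	+8q
430-MET-p30	-16q
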