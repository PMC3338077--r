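sample_id	series_id	patient_id	passage	origin	mirna_profiled	acgh_profiled
488-p1	488	488	1	primary_xenograft	TRUE	TRUE
488-p2	488	488	2	primary_xenograft	TRUE	TRUE
488-p4	488	488	4	primary_xenograft	FALSE	TRUE
488-p7	488	488	7	primary_xenograft	TRUE	TRUE
488-p11	488	488	11	primary_xenograft	FALSE	TRUE
488-p14	488	488	14	primary_xenograft	TRUE	TRUE
445-p0	445	445	0	primary_xenograft	FALSE	TRUE
445-p1	445	445	1	primary_xenograft	FALSE	TRUE
445-p4	445	445	4	primary_xenograft	FALSE	TRUE
445-p11	445	445	11	primary_xenograft	FALSE	TRUE
445-p15	445	445	15	primary_xenograft	FALSE	TRUE
445-p22	445	445	22	primary_xenograft	FALSE	TRUE
451-p0	451	451	0	primary_xenograft	FALSE	TRUE
451-p4	451	451	4	primary_xenograft	FALSE	TRUE
451-p11	451	451	11	primary_xenograft	TRUE	TRUE
451-p15	451	451	15	primary_xenograft	TRUE	TRUE
451-p18	451	451	18	primary_xenograft	FALSE	TRUE
451-p21	451	451	21	primary_xenograft	TRUE	TRUE
455-p0	455	455	0	primary_xenograft	FALSE	TRUE
455-p1	455	455	1	primary_xenograft	FALSE	TRUE
455-p5	455	455	5	primary_xenograft	TRUE	TRUE
455-p11	455	455	11	primary_xenograft	FALSE	TRUE
455-p17	455	455	17	primary_xenograft	FALSE	TRUE
455-p25	455	455	25	primary_xenograft	TRUE	TRUE
430-PRI-p0	430-PRI	430	0	primary_xenograft	FALSE	TRUE
430-PRI-p1	430-PRI	430	1	primary_xenograft	TRUE	TRUE
430-PRI-p4	430-PRI	430	4	primary_xenograft	FALSE	TRUE
430-PRI-p9	430-PRI	430	9	primary_xenograft	FALSE	TRUE
430-PRI-p19	430-PRI	430	19	primary_xenograft	TRUE	TRUE
430-MET-p1	430-MET	430	1	metastasis_xenograft	TRUE	TRUE
430-MET-p4	430-MET	430	4	metastasis_xenograft	FALSE	TRUE
430-MET-p14	430-MET	430	14	metastasis_xenograft	TRUE	TRUE
430-MET-p21	430-MET	430	21	metastasis_xenograft	FALSE	TRUE
430-MET-p30	430-MET	430	30	metastasis_xenograft	TRUE	TRUE
control_1	control	msc_1	0	control	TRUE	FALSE
control_2	control	msc_2	0	control	TRUE	FALSE
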