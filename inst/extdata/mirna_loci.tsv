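mirna_id	cytoband	direction	reported_count	expression_category
miR-765	1q23.1	gain	5	other
miR-135b	1q32.1	gain	5	other
miR-29c*	1q32.2	gain	5	other
miR-557	1q24.2	gain	6	exclusive_xeno
miR-215	1q41	gain	6	exclusive_xeno
miR-744	17p12	gain	1	exclusive_xeno
miR-195*	17p13.1	gain	1	exclusive_xeno
miR-451	17q11.2	gain	1	exclusive_xeno
miR-144	17q11.2	gain	1	exclusive_xeno
miR-454	17q22	gain	1	exclusive_xeno
miR-137	1p21.3	loss	2	other
miR-143*	5q32	loss	2	other
miR-143*	5q32	loss	2	other
miR-145*	5q32	loss	2	other
miR-145	5q32	loss	2	under
miR-31	9p21.3	loss	10	exclusive_control
miR-31*	9p21.3	loss	10	exclusive_control
miR-22	17p13.3	loss	3	under
miR-22*	17p13.3	loss	3	other
miR-503	Xq26.3	loss	2	other
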