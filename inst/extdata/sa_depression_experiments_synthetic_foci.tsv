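study_id	task_label	space	x	y	z	n_case	n_control	n_hc
Jollant2008	Happy_face	MNI	-42	18	-4	13	14	16
Jollant2008	Happy_face	MNI	36	24	-8	13	14	16
Jollant2008	Happy_face	MNI	-8	44	12	13	14	16
Jollant2008	Angry_face	MNI	40	22	-6	13	14	16
Jollant2008	Angry_face	MNI	-36	20	-2	13	14	16
Pan2011	Go_NoGo	MNI	8	30	28	15	15	14
Pan2011	Go_NoGo	MNI	-40	10	32	15	15	14
Pan2011	Go_NoGo	MNI	48	-60	8	15	15	14
Pan2013a	Happy_face	MNI	6	36	20	14	15	15
Pan2013a	Happy_face	MNI	-44	-28	50	14	15	15
Pan2013a	Happy_face	MNI	52	-48	4	14	15	15
Pan2013a	Angry_face	MNI	10	32	24	14	15	15
Pan2013a	Angry_face	MNI	-38	-24	54	14	15	15
Pan2013b	IGT	MNI	-30	22	-10	15	14	13
Pan2013b	IGT	MNI	26	40	-12	15	14	13
Vanyukov2016	Discounting_value	MNI	-10	12	6	13	13	22
Vanyukov2016	Discounting_value	MNI	12	10	4	13	13	22
Vanyukov2016	Discounting_delay	MNI	-12	14	8	13	13	22
Vanyukov2016	Discounting_delay	MNI	34	-18	56	13	13	22
Olie2017	Cyberball	MNI	-40	6	-6	36	41	28
Olie2017	Cyberball	MNI	44	10	-4	36	41	28
Olie2017	Cyberball	MNI	-6	-16	40	36	41	28
Ai2018	Faces	MNI	-22	-4	-18	18	54	26
Ai2018	Faces	MNI	24	-2	-20	18	54	26
Ji2021	BART	MNI	-34	-22	58	23	30	30
Ji2021	BART	MNI	8	-14	48	23	30	30
Ji2021	BART	MNI	-18	-34	-8	23	30	30
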