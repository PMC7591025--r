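family_id	group	exposed_parent	dose_gy	paternal_age	maternal_age	child_age	child_sex	md_father	md_mother	md_unknown	md_total	n_valid
Ct001	control	none	0	40	36	9	female	783	694	10	1487	702304
Ct25	control	none	0	47	36	9	male	545	631	3	1179	683381
Ct27	control	none	0	26	26	23	male	594	729	9	1332	692311
Ct39	control	none	0	24	24	3	female	679	679	11	1369	674320
Ct40	control	none	0	45	37	3	male	710	711	30	1451	696544
Ct45	control	none	0	37	31	15	male	643	663	8	1314	683243
Ct51	control	none	0	35	34	2	female	384	479	8	871	697737
Ct52	control	none	0	55	41	1	male	1015	588	32	1635	710477
Ct53	control	none	0	35	27	8	male	315	361	6	682	713372
Ct60	control	none	0	40	38	1	female	501	482	6	989	712261
Ct66	control	none	0	31	20	26	female	543	594	2	1139	707798
Ct68	control	none	0	33	20	10	male	758	654	11	1423	712191
Ct70	control	none	0	20	24	8	female	448	545	3	996	714892
Ct72	control	none	0	31	20	14	female	521	614	4	1139	710259
CtF09	control	none	0	19	21	25	male	718	696	9	1423	712352
Ex04	exposed	father	0.1	27	27	20	male	900	966	7	1873	698305
Ex06	exposed	father	0.3	35	26	9	male	1045	1082	9	2136	693858
Ex07-1F	exposed	mother	0.2	54	24	19	male	976	850	8	1834	692375
Ex07-4F	exposed	mother	0.2	56	26	17	female	1509	1085	18	2612	689467
Ex08	exposed	mother	0.2	18	20	8	male	538	718	4	1260	706759
Ex10	exposed	mother	0.2	21	24	2	female	1187	1054	21	2262	705993
Ex12	exposed	mother	0.3	31	30	3	male	1361	1486	28	2875	693463
Ex15	exposed	father	0.2	18	27	16	male	560	645	7	1212	706780
Ex18	exposed	father	0.2	47	30	18	male	819	800	12	1631	707366
Ex21	exposed	mother	0.2	38	27	20	female	457	513	2	972	707827
Ex22-2F	exposed	mother	0.2	29	31	20	female	1006	664	3	1673	707075
Ex22-3F	exposed	mother	0.2	32	34	17	female	845	566	3	1414	708278
Ex22-4F	exposed	mother	0.2	33	35	16	male	781	518	5	1304	708885
Ex24	exposed	father	0.5	21	19	12	female	1010	1102	47	2159	703635
Ex25	exposed	father	0.5	18	16	15	female	598	708	10	1316	706598
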