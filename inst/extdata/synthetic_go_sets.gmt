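inflammatory_response	synthetic set 1	HSYN0324	HSYN0227	HSYN1685	HSYN1354	HSYN1229	HSYN1484	HSYN0302	HSYN0441	HSYN0468	HSYN1169	HSYN0928	HSYN1167	HSYN1018	HSYN1012	HSYN0760	HSYN0308	HSYN0273	HSYN1026	HSYN1734	HSYN1486	HSYN0182	HSYN1308	HSYN1174	HSYN0872	HSYN0440	HSYN1660	HSYN0034	HSYN0867	HSYN0654
extracellular_matrix_organization	synthetic set 2	HSYN1398	HSYN1355	HSYN1325	HSYN0720	HSYN0410	HSYN1076	HSYN0858	HSYN0669	HSYN0563	HSYN0919	HSYN0600	HSYN1236	HSYN1474	HSYN1657	HSYN0795	HSYN0233	HSYN0155	HSYN1172	HSYN1577	HSYN1192	HSYN0947	HSYN0353	HSYN1395	HSYN0960	HSYN0284	HSYN0036	HSYN1010	HSYN0103	HSYN0929	HSYN1734	HSYN0620	HSYN0283	HSYN0332	HSYN0330	HSYN0514	HSYN1240
collagen_fibril_assembly	synthetic set 3	HSYN1338	HSYN0986	HSYN1322	HSYN1531	HSYN0899	HSYN1616	HSYN1369	HSYN1777	HSYN0017	HSYN1023	HSYN1690	HSYN1268	HSYN1397	HSYN1498	HSYN0038	HSYN0341	HSYN1561	HSYN0363	HSYN1136	HSYN0310	HSYN1385	HSYN0292	HSYN1370	HSYN1374	HSYN1273	HSYN0412	HSYN1304	HSYN1486	HSYN0136	HSYN0294	HSYN1798	HSYN1063	HSYN0260	HSYN0467	HSYN1552	HSYN0154	HSYN0831	HSYN1475	HSYN0911	HSYN1030	HSYN1133	HSYN1670	HSYN0945	HSYN0286
innate_immune_response	synthetic set 4	HSYN0105	HSYN1263	HSYN0554	HSYN1360	HSYN1518	HSYN0229	HSYN0743	HSYN0922	HSYN1146	HSYN0179	HSYN0401	HSYN0423	HSYN1368	HSYN0369	HSYN0835	HSYN1208	HSYN1131	HSYN0126	HSYN0474	HSYN1652	HSYN0929	HSYN0848	HSYN1061	HSYN1417	HSYN1656	HSYN0771	HSYN1123	HSYN0117	HSYN0467	HSYN1515	HSYN1134	HSYN1101	HSYN0343	HSYN1736	HSYN1701	HSYN1103	HSYN0484	HSYN0157	HSYN0800	HSYN1784	HSYN1550	HSYN1684	HSYN0821	HSYN0194	HSYN1537	HSYN0910	HSYN1158	HSYN0526	HSYN1610	HSYN1376	HSYN0750	HSYN0862	HSYN0799
epithelial_cell_differentiation	synthetic set 5	HSYN1146	HSYN0980	HSYN1210	HSYN1518	HSYN1029	HSYN1706	HSYN1028	HSYN0707	HSYN0201	HSYN0045	HSYN1503	HSYN1739	HSYN1656	HSYN1022	HSYN1307	HSYN0136	HSYN1623	HSYN1549	HSYN0247	HSYN0422	HSYN0479	HSYN0819	HSYN0395	HSYN0978	HSYN1056	HSYN1404	HSYN0934	HSYN0260	HSYN1446	HSYN0310	HSYN0404	HSYN0548
dna_replication	synthetic set 6	HSYN1440	HSYN0514	HSYN0379	HSYN0856	HSYN1646	HSYN1012	HSYN1193	HSYN0888	HSYN0204	HSYN0590	HSYN1426	HSYN0132	HSYN0328	HSYN0161	HSYN0900	HSYN0157	HSYN0133	HSYN1570	HSYN0173	HSYN1412	HSYN1698	HSYN0410	HSYN1471	HSYN1085	HSYN0113	HSYN1702	HSYN0457	HSYN1514	HSYN1375	HSYN1273	HSYN0198	HSYN0849	HSYN1022	HSYN1527	HSYN1170	HSYN0055	HSYN0596	HSYN0625	HSYN1591	HSYN1332	HSYN1303	HSYN0971	HSYN0661	HSYN0772	HSYN1094	HSYN0100	HSYN1404	HSYN0647	HSYN1708	HSYN0837	HSYN0533	HSYN1246	HSYN1737
keratinization	synthetic set 7	HSYN0601	HSYN1259	HSYN0551	HSYN1698	HSYN0873	HSYN0079	HSYN0331	HSYN1105	HSYN1633	HSYN1363	HSYN0152	HSYN0306	HSYN0871	HSYN0283	HSYN0898	HSYN0041	HSYN1033	HSYN0595	HSYN1467	HSYN0859	HSYN1222	HSYN1102	HSYN1682	HSYN1368	HSYN0526	HSYN0363	HSYN0200	HSYN0236	HSYN0374	HSYN0003	HSYN1049	HSYN0648	HSYN0149	HSYN1460	HSYN0242
cell_projection_morphogenesis	synthetic set 8	HSYN0027	HSYN0524	HSYN1229	HSYN0852	HSYN1284	HSYN1173	HSYN1706	HSYN1606	HSYN0535	HSYN1469	HSYN0138	HSYN1687	HSYN0426	HSYN0022	HSYN1710	HSYN0237	HSYN0835	HSYN1183	HSYN1273	HSYN0676	HSYN0677	HSYN0917	HSYN1149	HSYN1525	HSYN0096	HSYN1450	HSYN0923	HSYN1726	HSYN0247	HSYN1237	HSYN0378	HSYN0728	HSYN1108	HSYN0094	HSYN0583	HSYN0732	HSYN0894	HSYN1445	HSYN0220	HSYN1580	HSYN1636	HSYN0761	HSYN1125	HSYN1360	HSYN0554	HSYN0292	HSYN0111	HSYN1280	HSYN0593	HSYN1110	HSYN1448	HSYN1545	HSYN0878	HSYN1293	HSYN0169	HSYN1692	HSYN1616	HSYN1511	HSYN0579	HSYN1380
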