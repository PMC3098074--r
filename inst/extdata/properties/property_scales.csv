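"property","A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y","accession","description"
"1rsvol","31","55","54","83","132","3","96","111","119","111","105","56","32.5","85","124","32","61","84","170","136","GRAR740103","Residue volume (Grantham, 1974)"
"2chrg","0","0","-1","-1","0","0","0","0","1","0","0","0","0","0","1","0","0","0","0","0","","Net charge: R,K = +1; D,E = -1; others 0 (defined)"
"3achrg","0","0","1","1","0","0","0","0","1","0","0","0","0","0","1","0","0","0","0","0","","Absolute net charge: |2chrg| (defined)"
"4awrat","25","19","50","49","24","23","43","18","97","23","31","63","50","71","90","44","47","18","32","60","CHOC760102","Residue accessible surface area in folded protein (Chothia, 1976)"
"5arom","0","0","0","0","1","0","0","0","0","0","0","0","0","0","0","0","0","0","1","1","","Aromaticity: F,W,Y = 1; others 0 (defined)"
"6hdrp","0.31","1.54","-0.77","-0.64","1.79","0","0.13","1.8","-0.99","1.7","1.23","-0.6","0.72","-0.22","-1.01","-0.04","0.26","1.22","2.25","0.96","FAUJ830101","Hydrophobic parameter pi (Fauchere-Pliska, 1983)"
"7kbulk","11.5","13.46","11.68","13.57","19.8","3.4","13.69","21.4","15.71","21.4","16.25","12.82","17.43","14.45","14.28","9.47","15.77","21.57","21.67","18.03","ZIMJ680102","Bulkiness (Zimmerman et al., 1968)"
"8khdr2","-0.27","-1.05","0.81","1.17","-1.43","-0.16","0.28","-0.77","1.7","-1.1","-0.73","0.81","-0.75","1.1","1.87","0.42","0.63","-0.4","-1.57","-0.56","KIDA850101","Hydrophobicity-related index (Kidera et al., 1985)"
"9khdr3","1.8","2.5","-3.5","-3.5","2.8","-0.4","-3.2","4.5","-3.9","3.8","1.9","-3.5","-1.6","-3.5","-4.5","-0.8","-0.7","4.2","-0.9","-1.3","KYTJ820101","Hydropathy index (Kyte-Doolittle, 1982)"
"10khdr4","12.97","14.63","10.85","11.89","14","12.43","12.16","15.67","11.36","14.9","14.39","11.42","11.37","11.76","11.72","11.23","11.69","15.71","13.93","13.42","MANP780101","Average surrounding hydrophobicity (Manavalan-Ponnuswamy, 1978)"
"11kbpr1","0.83","1.19","0.54","0.37","1.38","0.75","0.87","1.6","0.74","1.3","1.05","0.89","0.55","1.1","0.93","0.75","1.19","1.7","1.37","1.47","CHOP780202","Normalized frequency of beta-sheet (Chou-Fasman, 1978)"
"12kbpr2","0.9","0.74","0.72","0.75","1.32","0.92","1.08","1.45","0.77","1.02","0.97","0.76","0.64","0.8","0.99","0.95","1.21","1.49","1.14","1.25","LEVM780102","Normalized frequency of beta-sheet, with weights (Levitt, 1978)"
"13kaprf","1.29","1.11","1.04","1.44","1.07","0.56","1.22","0.97","1.23","1.3","1.47","0.9","0.52","1.27","0.96","0.82","0.82","0.91","0.99","0.72","LEVM780101","Normalized frequency of alpha-helix, with weights (Levitt, 1978)"
"14kbnd1","0.6","1.29","1.24","0.64","1.05","1.38","0.95","0.67","1.1","0.7","0.67","1.42","1.47","0.92","0.79","1.26","1.05","0.48","1.23","1.35","CRAJ730103","Normalized frequency of turn (Crawford et al., 1973)"
"15kbnd2","0.79","0.79","1.47","1.02","0.77","1.67","0.81","0.5","0.99","0.57","0.51","1.25","1.78","0.92","0.9","1.3","0.97","0.46","0.79","0.93","LEVM780106","Normalized frequency of reverse turn, unweighted (Levitt, 1978)"
"16hydro","0.25","0.04","-0.72","-0.62","0.61","0.16","-0.4","0.73","-1.1","0.53","0.26","-0.64","-0.07","-0.69","-1.76","-0.26","-0.18","0.54","0.37","0.02","EISD840101","Consensus normalized hydrophobicity scale (Eisenberg, 1984)"
"17mass","89.09","121.15","133.1","147.13","165.19","75.07","155.16","131.17","146.19","131.17","149.21","132.12","115.13","146.15","174.2","105.09","119.12","117.15","204.24","181.19","FASG760101","Molecular weight (Fasman, 1976)"
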