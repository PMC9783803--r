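system,label,cp_type,rho,V_BCP,laplacian,H_BCP,E1
D1,ND-H...OA,BCP,0.0183,-0.0124,0.0790,0.0037,3.9029
D1,F...N,BCP,0.0110,-0.0089,0.0601,0.0031,2.7829
D1,ND-H,BCP,0.4652,-1.0418,-3.5875,-0.9694,-
D1,C=OA,BCP,0.4046,-1.3240,-0.5213,-0.7272,-
E1,OD-H...OA,BCP,0.0384,-0.0381,0.1349,-0.0022,11.9557
E1,OD-H,BCP,0.4178,-0.9894,-3.3106,-0.9085,-
E1,C=OA,BCP,0.4069,-1.3567,-0.4383,-0.7331,-
D2,ND-H...OA,BCP,0.0302,-0.0254,0.1031,0.0002,7.9586
D2,ND-H,BCP,0.3229,-0.5649,-1.8740,-0.5167,-
D2,C=OA,BCP,0.4074,-1.3773,-0.4297,-0.7423,-
E2,OD-H...OA,BCP,0.0522,-0.0554,0.1237,-0.0122,17.3707
E2,OD-H,BCP,0.3092,-0.6476,-2.0757,-0.5833,-
E2,C=OA,BCP,0.4058,-1.3759,-0.4073,-0.7388,-
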