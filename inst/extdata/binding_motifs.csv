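motif,frame,anchors
glp1_nterm_core,N,1=H;3=E;4=G;6=F;7=T;9=D
glp1_cterm_core,C,8=F;7=I;4=L;0=R
glp1_ortholog,N,2=A;3=E;5=T;7=T;13=Y;18=A;19=A;20=K;21=E;29=G
glucagon_ortholog,N,2=S;3=Q;5=T;13=Y;19=A
gip_ortholog,N,1=Y;3=E;8=S;11=S;24=N;27=L
glp1_paralog,N,1=H;4=G;6=F;9=D;14=L;22=F;23=I;25=W;26=L
glucagon_paralog,N,1=H;4=G;6=F;9=D;14=L;15=D;21=D;22=F;23=V;25=W;26=L
gip_paralog,N,4=G;6=F;9=D;15=D;21=D;22=F;23=V;25=W;26=L
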