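id,mutation,gene,diagnosis,group,is_consensus,ca_sens,tpm_stiffness,tn_shift_high,tn_shift_low,s1_shift_high,s1_shift_low,actin_on_tpm_high,actin_on_tpm_low,actin_on_s1_high,actin_on_s1_low,strong_high,strong_low,strong_atp_high,strong_atp_low
E41K_TPM2,E41K,TPM2,NM/Cap,Cap,FALSE,down,down,down,norm,down,up,norm,up,down,up,down,down,up,up
R90P_TPM3,R90P,TPM3,CFTD,CFTD,FALSE,up,up,up,up,down,up,down,up,down,down,up,up,down,up
R91G_TPM2,R91G,TPM2,DA,DA,FALSE,up,down,norm,norm,up,up,down,down,down,up,up,up,down,up
E117K_TPM2,E117K,TPM2,NM/CFTD/DA,NM,FALSE,down,up,missing,missing,missing,missing,missing,missing,missing,missing,down,down,down,down
E139del_TPM2,E139del,TPM2,Cap/CFTD,Cap,FALSE,up,down,up,up,up,up,up,down,up,down,down,up,down,up
Q147P_TPM2,Q147P,TPM2,Cap/NM,Cap,FALSE,up,down,up,up,up,up,down,up,down,down,down,up,down,up
E150A_TPM3,E150A,TPM3,Cap,CFTD,FALSE,up,down,down,up,up,up,up,up,up,up,up,up,down,up
A155T_TPM3,A155T,TPM3,NM,Cap,FALSE,up,down,norm,norm,up,up,norm,norm,up,up,down,up,down,up
A155T_TPM1,A155T,TPM1,none,unassigned,FALSE,missing,down,up,up,down,up,up,up,down,up,down,up,down,up
R167H_TPM1,R167H,TPM1,none,unassigned,FALSE,missing,up,down,up,down,norm,down,up,up,up,down,down,down,down
K168E_TPM1,K168E,TPM1,none,unassigned,FALSE,missing,up,norm,norm,down,down,down,down,norm,down,down,up,down,up
E173A_TPM3,E173A,TPM3,CFTD,CFTD,FALSE,up,down,up,up,up,up,up,up,up,up,up,up,up,up
consensus_CFTD,consensus,none,none,CFTD,TRUE,missing,missing,missing,missing,missing,missing,missing,missing,missing,missing,up,up,missing,missing
consensus_Cap,consensus,none,none,Cap,TRUE,missing,missing,missing,missing,missing,missing,missing,missing,missing,missing,down,up,missing,up
consensus_NM,consensus,none,none,NM,TRUE,missing,missing,missing,missing,missing,missing,missing,missing,missing,missing,down,down,missing,missing
consensus_DA,consensus,none,none,DA,TRUE,missing,missing,norm,norm,missing,missing,missing,missing,missing,missing,up,missing,missing,missing
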