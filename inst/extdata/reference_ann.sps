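COMPUTE Var1 = ((OxidHL * (-0.543086558961242)) + 3.63976611815824)
 + ((Pr_BD_ * (-5.67413921537257)) + 2.81153598121711)
 + ((LogBioHL * (0.40828801067156)) + 0.747514104338025)
 + ((ALogP * (-0.848110602763694)) + 1.43330691867064)
 + ((Sol * (-2.55399028293542E-02)) + 0.517313285798853)
 + ((MW * (1.40343495376914E-02)) - 5.94322423917294)
 + 3.86733992096867.
COMPUTE Var2 = ((OxidHL * (8.23491975851945E-02)) - 0.551904322215974)
 + ((Pr_BD_ * (3.12529587401663)) - 1.54858410557524)
 + ((LogBioHL * (0.431493610228662)) + 0.790000076287146)
 + ((ALogP * (-0.04107624611641)) + 6.94188559367329E-02)
 + ((Sol * (4.12997852313067E-02)) - 0.836531279838639)
 + ((MW * (1.05078568602304E-03)) - 0.444983569959981)
 + 9.28741349960935E-02.
COMPUTE Var3 = -0.535249116383622.
Execute.
COMPUTE Var1 = 0.108990429907616 * Var1.
COMPUTE Var2 = 1.44376333322051 * (Exp(Var2) - Exp(-Var2)) / (Exp(Var2) + Exp(-Var2)).
COMPUTE Var3 = Var3.
Execute.
COMPUTE Predicted_MRTD = ((((Var1 + Var2 + Var3)/2.0) + 0.5) * 199.9625) + 0.0375.
Execute.
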