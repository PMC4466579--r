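ext:V
ext:M
ext:V.M
surf:R2[p951=0,p1175=0,p1214=0]
surf:R2[p951=1,p1175=0,p1214=0]
surf:R2[p951=0,p1175=1,p1214=0]
surf:R2[p951=0,p1175=0,p1214=1]
surf:R2[p951=1,p1175=1,p1214=0]
surf:R2[p951=1,p1175=0,p1214=1]
surf:R2[p951=0,p1175=1,p1214=1]
surf:R2[p951=1,p1175=1,p1214=1]
surf:V.R2[p951=0,p1175=0,p1214=0]
surf:V.R2[p951=1,p1175=0,p1214=0]
surf:V.R2[p951=0,p1175=1,p1214=0]
surf:V.R2[p951=0,p1175=0,p1214=1]
surf:V.R2[p951=1,p1175=1,p1214=0]
surf:V.R2[p951=1,p1175=0,p1214=1]
surf:V.R2[p951=0,p1175=1,p1214=1]
surf:V.R2[p951=1,p1175=1,p1214=1]
surf:M.V.R2[p951=0,p1175=0,p1214=0]
surf:M.V.R2[p951=1,p1175=0,p1214=0]
surf:M.V.R2[p951=0,p1175=1,p1214=0]
surf:M.V.R2[p951=0,p1175=0,p1214=1]
surf:M.V.R2[p951=1,p1175=1,p1214=0]
surf:M.V.R2[p951=1,p1175=0,p1214=1]
surf:M.V.R2[p951=0,p1175=1,p1214=1]
surf:M.V.R2[p951=1,p1175=1,p1214=1]
surf:V.N1.R2[p951=0,p1175=0,p1214=0]
surf:V.N1.R2[p951=1,p1175=0,p1214=0]
surf:V.N1.R2[p951=0,p1175=1,p1214=0]
surf:V.N1.R2[p951=0,p1175=0,p1214=1]
surf:V.N1.R2[p951=1,p1175=1,p1214=0]
surf:V.N1.R2[p951=1,p1175=0,p1214=1]
surf:V.N1.R2[p951=0,p1175=1,p1214=1]
surf:V.N1.R2[p951=1,p1175=1,p1214=1]
surf:N1
surf:V.N1
rab45:R2[p951=0,p1175=0,p1214=0]
rab45:R2[p951=1,p1175=0,p1214=0]
rab45:R2[p951=0,p1175=1,p1214=0]
rab45:R2[p951=0,p1175=0,p1214=1]
rab45:R2[p951=1,p1175=1,p1214=0]
rab45:R2[p951=1,p1175=0,p1214=1]
rab45:R2[p951=0,p1175=1,p1214=1]
rab45:R2[p951=1,p1175=1,p1214=1]
rab45:V.R2[p951=0,p1175=0,p1214=0]
rab45:V.R2[p951=1,p1175=0,p1214=0]
rab45:V.R2[p951=0,p1175=1,p1214=0]
rab45:V.R2[p951=0,p1175=0,p1214=1]
rab45:V.R2[p951=1,p1175=1,p1214=0]
rab45:V.R2[p951=1,p1175=0,p1214=1]
rab45:V.R2[p951=0,p1175=1,p1214=1]
rab45:V.R2[p951=1,p1175=1,p1214=1]
rab45:V.N1.R2[p951=0,p1175=0,p1214=0]
rab45:V.N1.R2[p951=1,p1175=0,p1214=0]
rab45:V.N1.R2[p951=0,p1175=1,p1214=0]
rab45:V.N1.R2[p951=0,p1175=0,p1214=1]
rab45:V.N1.R2[p951=1,p1175=1,p1214=0]
rab45:V.N1.R2[p951=1,p1175=0,p1214=1]
rab45:V.N1.R2[p951=0,p1175=1,p1214=1]
rab45:V.N1.R2[p951=1,p1175=1,p1214=1]
rab45:N1
rab45:V.N1
rab45:V
rab11:R2[p951=0,p1175=0,p1214=0]
rab11:R2[p951=1,p1175=0,p1214=0]
rab11:R2[p951=0,p1175=1,p1214=0]
rab11:R2[p951=0,p1175=0,p1214=1]
rab11:R2[p951=1,p1175=1,p1214=0]
rab11:R2[p951=1,p1175=0,p1214=1]
rab11:R2[p951=0,p1175=1,p1214=1]
rab11:R2[p951=1,p1175=1,p1214=1]
rab11:V.R2[p951=0,p1175=0,p1214=0]
rab11:V.R2[p951=1,p1175=0,p1214=0]
rab11:V.R2[p951=0,p1175=1,p1214=0]
rab11:V.R2[p951=0,p1175=0,p1214=1]
rab11:V.R2[p951=1,p1175=1,p1214=0]
rab11:V.R2[p951=1,p1175=0,p1214=1]
rab11:V.R2[p951=0,p1175=1,p1214=1]
rab11:V.R2[p951=1,p1175=1,p1214=1]
rab11:V.N1.R2[p951=0,p1175=0,p1214=0]
rab11:V.N1.R2[p951=1,p1175=0,p1214=0]
rab11:V.N1.R2[p951=0,p1175=1,p1214=0]
rab11:V.N1.R2[p951=0,p1175=0,p1214=1]
rab11:V.N1.R2[p951=1,p1175=1,p1214=0]
rab11:V.N1.R2[p951=1,p1175=0,p1214=1]
rab11:V.N1.R2[p951=0,p1175=1,p1214=1]
rab11:V.N1.R2[p951=1,p1175=1,p1214=1]
rab11:N1
rab11:V.N1
rab11:V
degr:V
degr:R2
degr:N1
degr:V.R2
degr:V.N1
degr:V.N1.R2
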