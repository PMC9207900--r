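# GEMM exposure-response parameters for non-accidental mortality
# (non-communicable disease + lower respiratory infection, NCD+LRI),
# RR(z) = exp(theta * log(1 + z/alpha) / (1 + exp(-(z - mu)/nu))),
# z = max(0, C - counterfactual). Published Burnett-style values shipped
# as an overridable fixture; shape constants (alpha, mu, nu) are common
# across ages, theta declines with age.
counterfactual: 2.4   # ug/m3, minimum exposure of no excess risk
alpha: 1.6            # ug/m3
mu: 15.5              # ug/m3
nu: 36.8              # ug/m3
all_age:
  theta: 0.1430
  theta_se: 0.01807
age_specific:
  "25-29": {theta: 0.1585, theta_se: 0.01477}
  "30-34": {theta: 0.1577, theta_se: 0.01470}
  "35-39": {theta: 0.1570, theta_se: 0.01463}
  "40-44": {theta: 0.1558, theta_se: 0.01450}
  "45-49": {theta: 0.1532, theta_se: 0.01425}
  "50-54": {theta: 0.1499, theta_se: 0.01394}
  "55-59": {theta: 0.1462, theta_se: 0.01361}
  "60-64": {theta: 0.1421, theta_se: 0.01325}
  "65-69": {theta: 0.1374, theta_se: 0.01284}
  "70-74": {theta: 0.1319, theta_se: 0.01234}
  "75-79": {theta: 0.1253, theta_se: 0.01174}
  "80+":   {theta: 0.1141, theta_se: 0.01071}
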