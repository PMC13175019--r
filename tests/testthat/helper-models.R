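# Shared fixtures: the two calibrated genotype models and a passive RC cell.
ctrl_model <- function() neuron_model(f_s = 0.56)
ex3d_model <- function() neuron_model(f_s = 0.22)

passive_model <- function(g_leak = 1, e_leak = -60, cm = 40) {
  neuron_model(g_na = 0, g_kdr = 0, g_cal = 0, g_sk = 0, g_hcn = 0,
               kv4 = kv4_params(g_max = 0),
               g_leak = g_leak, e_leak = e_leak, cm = cm)
}

# toy peptide table builder
toy_peptides <- function(pvs, protein = "KChIP4", specific = TRUE,
                         assigned = TRUE, dataset = "d1") {
  data.frame(peptide = paste0("pep", seq_along(pvs)), protein = protein,
             specific = specific, assigned = assigned, pv = pvs,
             dataset = dataset)
}
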