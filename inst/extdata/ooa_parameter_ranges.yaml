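# Literature-informed ranges for the 25 free parameters of the five-population
# Out-of-Africa model (Gutenkunst/Gravel-era human demographic inference).
# Units: diploid population sizes; times in generations before present;
# growth and migration rates per generation. Each entry is [low, high]; grid
# searches start from the midpoint of each range.
N_AFR_anc: [5000, 20000]
tau_BANTU: [75, 225]
r_AFR: [0.0, 0.015]
tau_OOA: [1500, 4000]
B_EURASI: [0.05, 0.45]
N_EURASI: [1000, 10000]
tau_EUR: [600, 1300]
B_EUR: [0.05, 0.45]
N_EUR: [2000, 20000]
r_EUR: [0.0, 0.005]
tau_EAS: [600, 1300]
B_EAS: [0.05, 0.45]
N_EAS: [2000, 20000]
r_EAS: [0.0, 0.005]
tau_SAS: [600, 1300]
B_SAS: [0.05, 0.45]
N_SAS: [2000, 20000]
r_SAS: [0.0, 0.005]
m_AFR_EURASI: [0.0, 0.0005]
m_AFR_EUR: [0.0, 0.0005]
m_AFR_EAS: [0.0, 0.0005]
m_AFR_SAS: [0.0, 0.0005]
m_EUR_EAS: [0.0, 0.0005]
m_EUR_SAS: [0.0, 0.0005]
m_EAS_SAS: [0.0, 0.0005]
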