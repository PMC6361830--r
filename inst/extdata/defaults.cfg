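C_m = 200
g_L = 8
E_L = -65
g_D = 4
E_K = -90
m_dtau = 0.6
h_dtau = 1500
V_T = -50
v_R = -85
v_init = -75
g_Exc = 5.5
g_Excr = 50
E_Exc = 0
beta = 0.2
g_Inh = 0.02
E_Inh = -100
m_d0 = 0
h_d0 = 1
n_cells = 60
dt = 0.05
t_max = 150000
stim_amplitude = 4
stim_onset = 0
stim_duration = Inf
sd_gD = 0.03
sd_gExc = 0.15
draw = per_trial
g_noise = 0
beta_n = 0.1
n_presyn = 100
rate_hz = 50
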