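# Neural-mass and prior constants for the spectral DCM forward model.
# version 1: ERP-convolution model with Jansen-Rit kinetics. All fitted
# parameters are log scalings of these values with Gaussian shrinkage priors
# (mean 0); a prior variance of 0 marks a quantity that is fixed by default.
version: 1
neural:
  He: 4.0        # excitatory synaptic gain (mV)
  Hi: 32.0       # inhibitory synaptic gain (mV)
  tau_e: 0.010   # excitatory synaptic time constant (s)
  tau_i: 0.016   # inhibitory synaptic time constant (s)
  gamma: [128.0, 102.4, 32.0, 32.0]  # intrinsic gains g1..g4 (stellate<-pyr, pyr<-stellate, interneuron<-pyr, pyr<-interneuron)
  sigmoid_slope: 0.56                # slope r of centred sigmoid 1/(1+exp(-r v)) - 1/2
coupling:
  # base extrinsic gains by edge type; forward connections target the granular
  # (spiny stellate) population, backward target pyramidal and inhibitory
  # interneuron populations (modulatory/inhibitory weighted), lateral target all
  forward: 32.0
  backward: 16.0
  lateral: 4.0
innovations:
  # per-source neuronal innovations one-sided PSD:
  #   Gu(f) = amp * exp(a_amp) * (white_frac + (1-white_frac) * f^(-exp(a_exp)))
  amp: 1.0
  white_frac: 0.5
observation:
  # channel noise PSD, same white + 1/f^beta mixture; "common" is shared across
  # channels (rank-one, all-ones spatial profile), "specific" is per-channel
  common_amp: 1.0e-5
  specific_amp: 1.0e-5
  white_frac: 0.5
priors:
  # prior variances of the log-scaling parameters (mean 0 throughout)
  a: 0.25              # 12 extrinsic couplings
  intrinsic: 0.0       # He, Hi, tau_e, tau_i, gamma1..4 per source (fixed: extrinsic-only fitting)
  sigmoid: 0.0
  innovations_amp: 0.5
  innovations_exp: 0.0
  lead_gain: 0.0
  noise_amp: 0.5
  noise_exp: 0.0
hyperpriors:
  # log noise-precision hyperpriors per feature block (real / imaginary parts)
  mean: 4.0
  variance: 16.0
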