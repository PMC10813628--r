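sample_id,mud,sand,gravel,fine,medium,coarse,hard_cover_pct
st01,0.42,0.55,0.03,0.30,0.20,0.05,NA
st02,0.03,0.92,0.05,0.70,0.15,0.07,NA
st03,0.10,0.55,0.35,0.10,0.20,0.25,NA
st04,0.05,0.15,0.80,0.05,0.05,0.05,NA
st05,0.02,0.38,0.60,0.10,0.10,0.18,45
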