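# Example pipeline configuration for read_pipeline_config()
profile: reduced
cohort_seed: 1
split_ratio: 0.6
cv_k: 10
cv_repeats: 10
families: [rsf, boosted_cox]
censor_quantile: 0.995
tune: true
fit_cph_comparison: true
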