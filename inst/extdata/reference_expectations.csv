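check,expected,tolerance,source
mlr_abacavir_pred,-10.6738,0.001,test prediction table
mlr_nevirapine_pred,-54.1862,0.001,test prediction table
mlr_test_mean,-0.1105,0.001,test prediction table
mlr_test_rmse,27.27,0.05,test prediction table
mlr_max_sq_error,3270.26,1.0,test prediction table
ann_abacavir_pred,6.4861,0.01,test prediction table
ann_lopiravir_pred,64.59,0.01,test prediction table
ann_test_rmse,13.67,0.05,test prediction table
ann_max_sq_error,601.23,1.0,test prediction table
tau_mlr,0.714,0.001,rank correlation
tau_ann,0.643,0.001,rank correlation
mlr_loa_upper,58.3,0.1,limits of agreement
mlr_loa_lower,-17.4,0.1,limits of agreement
ann_loa_upper,29.8,0.1,limits of agreement
ann_loa_lower,-27.3,0.1,limits of agreement
ols_r2,0.5970,0.010,training refit
ols_mcc,0.7727,0.007,training refit
ols_rsd,33.89,0.05,training refit
ols_f_ratio,3.9507,0.10,training refit
ols_p_asol,0.0140,0.005,training refit
ols_p_pbd,0.0349,0.005,training refit
ann_train_rmse,5.53,0.05,training fit of reference network
ann_train_max_abs_error,13.64,0.05,training fit of reference network
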