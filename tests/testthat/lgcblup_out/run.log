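20:37:22 lgcblup 0.1.0 | subcommand: frobnicate | seed: 1
20:37:22 config: plink_prefix=NULL pheno_file=NULL trait=NULL block_file=NULL out_dir=lgcblup_out scenario=heterogeneous n_per_pop=NULL seed=1 max_missing_rate=0.01 min_maf=0.05 hwe_p_floor=1e-06 max_block_snps=60 min_snps=25 window=50 top_k=20 lgc_threshold=0.5 models=STGBLUP,MTGBLUP cv_k=10 cv_repeats=10 refit_classes=TRUE commensurable=TRUE
20:39:28 lgcblup 0.1.0 | subcommand: frobnicate | seed: 1
20:39:28 config: plink_prefix=NULL pheno_file=NULL trait=NULL block_file=NULL out_dir=lgcblup_out scenario=heterogeneous n_per_pop=NULL seed=1 max_missing_rate=0.01 min_maf=0.05 hwe_p_floor=1e-06 max_block_snps=60 min_snps=25 window=50 top_k=20 lgc_threshold=0.5 models=STGBLUP,MTGBLUP cv_k=10 cv_repeats=10 refit_classes=TRUE commensurable=TRUE
20:40:09 lgcblup 0.1.0 | subcommand: frobnicate | seed: 1
20:40:09 config: plink_prefix=NULL pheno_file=NULL trait=NULL block_file=NULL out_dir=lgcblup_out scenario=heterogeneous n_per_pop=NULL seed=1 max_missing_rate=0.01 min_maf=0.05 hwe_p_floor=1e-06 max_block_snps=60 min_snps=25 window=50 top_k=20 lgc_threshold=0.5 models=STGBLUP,MTGBLUP cv_k=10 cv_repeats=10 refit_classes=TRUE commensurable=TRUE
21:48:47 lgcblup 0.1.0 | subcommand: frobnicate | seed: 1
21:48:47 config: plink_prefix=NULL pheno_file=NULL trait=NULL block_file=NULL out_dir=lgcblup_out scenario=heterogeneous n_per_pop=NULL seed=1 max_missing_rate=0.01 min_maf=0.05 hwe_p_floor=1e-06 max_block_snps=60 min_snps=25 window=50 top_k=20 lgc_threshold=0.5 models=STGBLUP,MTGBLUP cv_k=10 cv_repeats=10 refit_classes=TRUE commensurable=TRUE
22:06:28 lgcblup 0.1.0 | subcommand: frobnicate | seed: 1
22:06:28 config: plink_prefix=NULL pheno_file=NULL trait=NULL block_file=NULL out_dir=lgcblup_out scenario=heterogeneous n_per_pop=NULL seed=1 max_missing_rate=0.01 min_maf=0.05 hwe_p_floor=1e-06 max_block_snps=60 min_snps=25 window=50 top_k=20 lgc_threshold=0.5 models=STGBLUP,MTGBLUP cv_k=10 cv_repeats=10 refit_classes=TRUE commensurable=TRUE
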