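feature_table=NULL
design=NULL
library=NULL
out_dir=ms1stoich_out
simulate=TRUE
n_features=120
blank_filter=TRUE
blank_ratio=3
blank_stat=mean
is_cv_limit=30
ppm=NA
min_isotope_score=30
max_candidates=3
composite_mode=average-counts
iqr_drop_fraction=0.25
presence_fraction=0.5
alpha=0.05
min_abs_log2fc=1
p_adjust=BH
n_components=2
folds=5
seed=0
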