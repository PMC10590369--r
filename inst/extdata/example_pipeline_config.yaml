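# Example end-to-end configuration for read_pipeline_config(): a small
# synthetic study with three planted clusters over a 22-week spring window.
synthetic:
  n_actors: 30
  n_weeks: 22
  n_clusters: 3
  n_topics_true: 3
  events_per_week_mean: 120
  seed: 42
weeks: [1, 22]
year: 2019
topic_range: [2, 3, 4, 5]
n_inits: 2
master_seed: 1
k: 3
theme_group: ["topic_1"]
out_dir: "traceproc_example_run"
render_figures: no
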