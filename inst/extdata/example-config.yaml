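# Example pipeline configuration for the grainsight CLI.
anchors:
  scales: [8, 16, 24, 32, 48]
  ratios: [1.0, 0.5, 2.0]
  stride: 16
suppress:
  mode: gaussian   # hard | linear | gaussian
  Nt: 0.3
  sigma: 0.5
  floor: 0.001
pspm:
  k: 3
train:
  lr: 0.0005
  epochs: 100
  lr_decay: 0.1
  weight_decay: 0.0005
  pre_nms: 2000
  post_nms: 600
  roi_pos_iou: 0.5
  seed: 1
scene:
  width: 640
  height: 480
  classes: {Rfb: 0.5, Cfb: 0.5}
  count_range: [1, 7]
  size_range: [8, 48]
  aspect_range: [0.3, 2.2]
  cluster_prob: 0.25
  difficult_prob: 0.02
  seed: 1
arch: mcs
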