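# Frozen reference configuration of the multi-channel Swin-UNet.
# Calibrated so that the trainable-parameter count is exactly 4,990,032.
input_size: 48
patch_size: 4
in_channels: 8
filters_per_channel: 12
window_size: 6
shift_size: 3
stage_depths: [2, 2, 2]
heads_per_stage: [4, 4, 8]
mlp_ratio: [4, 2, 2]
num_classes: 11
use_relative_position_bias: true
qkv_bias: true
embed_pointwise: false
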