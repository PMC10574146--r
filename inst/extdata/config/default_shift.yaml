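# Default season shift (source -> target domain). Version: 2
#
# Brightness-led: a strong brightness/saturation reduction with a small
# hue rotation and a mild texture-contrast stretch. Calibrated once so
# that a source-trained toy net screens as "skip" (WKs > 0.8) on source
# scenes and "transfer" (WKs < 0.6) on shifted scenes, then frozen.
hue_shift: 20
brightness_gain: 0.60
saturation_gain: 0.75
texture_contrast_gain: 1.2
per_class_flags: [true, true, true, false]  # tree, shrub, grass, NVA
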