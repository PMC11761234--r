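region,criterion,mirror_n,template_n,n
labial,1,16,24,24
mandibular_angle,1,22,24,24
cheek,1,16,24,24
chin,1,18,24,24
articular,1,19,24,24
labial,2,17,24,24
mandibular_angle,2,21,24,24
cheek,2,16,24,24
chin,2,18,24,24
articular,2,24,24,24
labial,3,21,24,24
mandibular_angle,3,23,24,24
cheek,3,21,24,24
chin,3,22,24,24
articular,3,24,24,24
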