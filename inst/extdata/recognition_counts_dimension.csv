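region,axis,criterion,mirror_n,template_n,n
labial,X,1,14,21,24
labial,Y,1,3,23,24
labial,Z,1,11,24,24
mandibular_angle,X,1,22,22,24
mandibular_angle,Y,1,14,22,24
mandibular_angle,Z,1,6,23,24
cheek,X,1,7,19,24
cheek,Y,1,3,22,24
cheek,Z,1,16,19,24
chin,X,1,20,20,24
chin,Y,1,7,21,24
chin,Z,1,11,22,24
articular,X,1,19,21,24
articular,Y,1,3,22,24
articular,Z,1,5,21,24
labial,X,2,14,21,24
labial,Y,2,14,23,24
labial,Z,2,16,24,24
mandibular_angle,X,2,21,22,24
mandibular_angle,Y,2,18,22,24
mandibular_angle,Z,2,17,23,24
cheek,X,2,10,19,24
cheek,Y,2,7,22,24
cheek,Z,2,14,19,24
chin,X,2,18,20,24
chin,Y,2,18,21,24
chin,Z,2,17,22,24
articular,X,2,22,21,24
articular,Y,2,17,22,24
articular,Z,2,16,21,24
labial,X,3,19,21,24
labial,Y,3,19,23,24
labial,Z,3,21,24,24
mandibular_angle,X,3,23,22,24
mandibular_angle,Y,3,22,22,24
mandibular_angle,Z,3,20,23,24
cheek,X,3,20,19,24
cheek,Y,3,13,22,24
cheek,Z,3,20,19,24
chin,X,3,22,20,24
chin,Y,3,22,21,24
chin,Z,3,20,22,24
articular,X,3,24,21,24
articular,Y,3,21,22,24
articular,Z,3,20,21,24
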