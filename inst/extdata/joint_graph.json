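{"node_names":["sacrum","spine_center","neck","head","shoulder_left","elbow_left","wrist_left","hand_left","shoulder_right","elbow_right","wrist_right","hand_right","hip_left","knee_left","ankle_left","foot_left","hip_right","knee_right","ankle_right","foot_right","shoulder_center","handtip_left","thumb_left","handtip_right","thumb_right"],"edges_flat":[0,1,1,20,20,2,2,3,20,4,4,5,5,6,6,7,7,21,7,22,20,8,8,9,9,10,10,11,11,23,11,24,0,12,12,13,13,14,14,15,0,16,16,17,17,18,18,19],"selection_map":[0,1,3,26,5,6,7,8,12,13,14,15,18,19,20,21,22,23,24,25,2,9,10,16,17]}
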