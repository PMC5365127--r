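landmark,x,y
forehead,345,616
throat,345,560
left_shoulder,314,545
right_shoulder,376,545
left_elbow,300,482
right_elbow,390,482
left_hand,339,430
right_hand,351,430
left_hip,325,332
right_hip,365,332
centre_of_gravity,345,341
sternum,345,520
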