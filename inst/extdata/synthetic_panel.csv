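rater,standing_long_jump,height,leg_length_ratio,state_anxiety,shoe_size,favourite_music_tempo
expert1,5,4,4,4,2,1
expert2,5,5,4,3,3,2
expert3,4,4,5,4,2,1
expert4,5,4,4,4,3,2
expert5,4,5,4,5,1,3
expert6,5,4,4,4,2,1
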