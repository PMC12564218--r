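subscale,item_id
general_health,1
general_vision,2
ocular_pain,4
ocular_pain,19
near_activities,5
near_activities,6
near_activities,7
distance_activities,8
distance_activities,9
distance_activities,14
social_functioning,11
social_functioning,13
mental_health,3
mental_health,21
mental_health,22
mental_health,25
role_difficulties,17
role_difficulties,18
dependency,20
dependency,23
dependency,24
driving,15c
driving,16
driving,16a
color_vision,12
peripheral_vision,10
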