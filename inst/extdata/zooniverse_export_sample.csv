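classification_id,user_name,user_id,workflow_version,created_at,subject_ids,annotations,metadata
501,alice,11,16.14,2022-03-01 10:00:00,7001,"[{""task"":""T0"",""value"":[{""x"":241.5,""y"":10,""tool"":0},{""x"":630.25,""y"":12,""tool"":1}]}]","{""viewport"":{""width"":1536}}"
502,bob,12,16.14,2022-03-01 11:30:00,7001,"[{""task"":""T0"",""value"":[{""x"":244,""y"":11,""tool"":0}]}]","{""viewport"":{""width"":1536}}"
503,alice,11,16.14,2022-03-02 09:15:00,7001,"[{""task"":""T0"",""value"":[{""x"":250,""y"":10,""tool"":0}]}]","{""viewport"":{""width"":1536}}"
504,carol,13,16.14,2022-03-03 14:00:00,7002,"[{""task"":""T0"",""value"":[]}]","{""viewport"":{""width"":1536}}"
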