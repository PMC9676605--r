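patient_id,age,sex,total_bilirubin_mgdl,lft_abnormal,cbd_diameter_mm,stone_on_imaging,cholangitis,ercp_stone
P001,32,male,4.8,1,11.5,1,1,1
P002,39,female,5.6,1,12,1,1,1
P003,46,male,6.3,1,12.5,1,1,1
P004,53,female,4.8,1,11.5,1,1,1
P005,60,male,5.6,1,12,1,1,1
P006,67,female,6.3,1,12.5,1,1,1
P007,28,male,4.8,1,11.5,1,1,1
P008,35,female,5.6,1,12,1,1,1
P009,42,male,6.3,1,12.5,1,1,1
P010,49,female,4.8,1,11.5,1,1,1
P011,56,male,2.8,1,10.5,0,1,1
P012,63,female,2.2,1,8,1,0,1
P013,70,male,2.6,1,8.8,1,0,1
P014,31,female,3.1,1,9.6,1,0,1
P015,38,male,2.2,1,10.4,1,0,1
P016,45,female,2.6,1,11.2,1,0,1
P017,52,male,3.1,1,8,1,0,1
P018,59,female,2.2,1,8.8,1,0,1
P019,66,male,2.6,1,9.6,1,0,1
P020,27,female,3.1,1,10.4,1,0,1
P021,34,male,2.2,1,11.2,1,0,1
P022,41,female,2.6,1,8,1,0,1
P023,48,male,3.1,1,8.8,1,0,1
P024,55,female,2.2,1,9.6,1,0,1
P025,62,male,2.6,1,10.4,1,0,1
P026,69,female,3.1,1,11.2,1,0,1
P027,30,male,2.2,1,8,1,0,1
P028,37,female,2.6,1,8.8,1,0,1
P029,44,male,3.1,1,9.6,1,0,1
P030,51,female,2.2,1,10.4,1,0,1
P031,58,male,2.6,1,11.2,1,0,1
P032,65,female,3.1,1,8,1,0,1
P033,26,male,2.2,1,8.8,1,0,1
P034,33,female,2.6,1,9.6,1,0,1
P035,40,male,3.1,1,10.4,1,0,1
P036,47,female,2.2,1,11.2,1,0,1
P037,54,male,2.6,1,8,1,0,1
P038,61,female,3.1,1,8.8,1,0,1
P039,68,male,2.2,1,9.6,1,0,1
P040,29,female,2.6,1,10.4,1,0,1
P041,36,male,3.1,1,11.2,1,0,1
P042,43,female,2.2,1,8,1,0,1
P043,50,male,2.6,1,8.8,1,0,1
P044,57,female,3.1,1,9.6,1,0,1
P045,64,male,2.2,1,10.4,1,0,1
P046,25,female,2.6,1,11.2,1,0,1
P047,32,male,3.1,1,8,1,0,1
P048,39,female,2.2,1,8.8,1,0,1
P049,46,male,2.6,1,9.6,1,0,1
P050,53,female,3.1,1,10.4,1,0,1
P051,60,male,2.2,1,11.2,1,0,1
P052,67,female,2.6,1,8,1,0,1
P053,28,male,3.1,1,8.8,1,0,1
P054,35,female,2.2,1,9.6,1,0,1
P055,42,male,2.6,1,10.4,1,0,1
P056,49,female,3.1,1,11.2,1,0,1
P057,38,male,1,0,5.2,1,0,1
P058,63,female,1.2,1,5.8,1,0,1
P059,70,male,1.1,1,9,0,0,1
P060,31,female,1.1,1,9,0,0,1
P061,38,male,1.4,1,8.5,1,0,0
P062,45,female,1.4,1,9,1,0,0
P063,52,male,1.4,1,8.5,1,0,0
P064,59,female,1.4,1,9,1,0,0
P065,66,male,1.4,1,8.5,1,0,0
P066,27,female,1.4,1,9,1,0,0
P067,34,male,1.4,1,8.5,1,0,0
P068,41,female,1.4,1,9,1,0,0
P069,48,male,1.4,1,8.5,1,0,0
P070,55,female,4.6,1,11,0,0,0
P071,62,female,3,1,8,0,0,0
P072,69,female,3,1,8,0,0,0
P073,30,female,3,1,8,0,0,0
P074,37,female,1.2,0,7.5,0,0,0
P075,44,female,1.2,0,7.5,0,0,0
P076,51,female,1.2,0,7.5,0,0,0
P077,58,female,1.2,0,7.5,0,0,0
P078,65,female,1.2,0,7.5,0,0,0
P079,26,female,1.2,0,7.5,0,0,0
P080,33,female,2.5,1,5.5,0,0,0
P081,40,female,2.5,1,5.5,0,0,0
P082,47,female,2.5,1,5.5,0,0,0
P083,54,female,2.5,1,5.5,0,0,0
P084,61,female,2.5,1,5.5,0,0,0
P085,68,female,2.5,1,5.5,0,0,0
P086,29,female,2.5,1,5.5,0,0,0
P087,36,female,2.5,1,5.5,0,0,0
P088,43,female,2.5,1,5.5,0,0,0
P089,36,female,0.8,0,4.5,0,0,0
P090,42,female,0.8,0,5,0,0,0
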